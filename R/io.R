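plate_required_cols <- c("sample_id", "replicate", "assay", "reaction_type",
                         "cq")
plate_optional_cols <- c("site", "season", "stream_class", "known_copies",
                         "salinity")
reaction_types <- c("standard", "unknown", "ntc", "ipc_control", "ipc_sample")

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a qPCR plate table
#'
#' Reads a delimited plate table (CSV by extension, otherwise TSV) with one
#' row per reaction. Required columns: `sample_id`, `replicate`, `assay`,
#' `reaction_type`, `cq`; optional: `site`, `season`, `stream_class`,
#' `known_copies`, `salinity`. A `cq` cell that is empty or the literal
#' `ND` is a non-detect and becomes `NA`. Row-level violations (negative
#' or zero Cq, unknown reaction type, replicate < 1, `known_copies`
#' present/absent inconsistently with the standard reaction type) raise an
#' error naming the offending rows.
#'
#' @param path Path to the table.
#' @return Typed plate data frame.
#' @export
read_plate_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(plate_required_cols, names(raw))
  if (length(missing_cols) > 0L)
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  num <- function(x) suppressWarnings(as.numeric(ifelse(
    is.na(x) | trimws(x) %in% c("", "ND", "NA"), NA, x)))
  plate <- raw
  plate$replicate <- as.integer(num(raw$replicate))
  plate$cq <- num(raw$cq)
  if ("known_copies" %in% names(raw)) plate$known_copies <- num(raw$known_copies)
  if ("salinity" %in% names(raw)) plate$salinity <- num(raw$salinity)
  for (col in c("site", "season", "stream_class"))
    if (col %in% names(plate))
      plate[[col]] <- ifelse(trimws(plate[[col]]) == "", NA, plate[[col]])

  problems <- character(0)
  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems, sprintf(
        "%s (rows %s)", what,
        paste(utils::head(which(rows), 10L), collapse = ", ")))
  }
  bad(!is.na(plate$cq) & plate$cq <= 0, "non-positive Cq")
  bad(!plate$reaction_type %in% reaction_types, "unknown reaction_type")
  bad(is.na(plate$replicate) | plate$replicate < 1L, "replicate < 1")
  is_std <- plate$reaction_type == "standard"
  if ("known_copies" %in% names(plate)) {
    bad(is_std & is.na(plate$known_copies), "standard without known_copies")
    bad(is_std & !is.na(plate$known_copies) & plate$known_copies <= 0,
        "non-positive known_copies")
    bad(!is_std & !is.na(plate$known_copies),
        "known_copies on a non-standard reaction")
  } else if (any(is_std)) {
    problems <- c(problems, "standard rows but no known_copies column")
  }
  if (length(problems) > 0L)
    stop("row error(s) in ", path, ": ", paste(problems, collapse = "; "),
         call. = FALSE)
  plate
}

#' Write a qPCR plate table
#'
#' Writes a plate data frame in the dialect [read_plate_table()] reads;
#' non-detect Cq values are written as `ND`. CSV or TSV by file extension.
#'
#' @param plate Plate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plate, path) {
  out <- plate
  out$cq <- ifelse(is.na(out$cq), "ND", format(out$cq, digits = 15))
  utils::write.table(out, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline: the volume
#' configuration, the LOD detection-probability target (0.95), the LOQ CV
#' threshold (0.35), the inhibition significance threshold (3 cycles), the
#' rule for negative replicates in group means, the multiplicity
#' adjustment, and the seed.
#'
#' @param volumes A [volume_config()].
#' @param lod_probability LOD detection-probability target, in (0, 1).
#' @param loq_cv_threshold LOQ CV threshold, > 0.
#' @param inhibition_threshold Significant-inhibition threshold, cycles.
#' @param negative_fill `"zero_fill"` or `"omit"` (see
#'   [summarize_survey()]).
#' @param p_adjust `"holm"`, `"bonferroni"`, or `"none"`.
#' @param clip_negative_delta Clip negative inhibition delays to zero.
#' @param lod_method `"modeled"` or `"discrete"`.
#' @param seed Optional integer seed recorded in reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(volumes = volume_config(),
                            lod_probability = 0.95,
                            loq_cv_threshold = 0.35,
                            inhibition_threshold = 3,
                            negative_fill = c("zero_fill", "omit"),
                            p_adjust = c("holm", "bonferroni", "none"),
                            clip_negative_delta = FALSE,
                            lod_method = c("modeled", "discrete"),
                            seed = NULL) {
  stopifnot(lod_probability > 0, lod_probability < 1, loq_cv_threshold > 0,
            inhibition_threshold > 0)
  structure(list(volumes = volumes,
                 lod_probability = lod_probability,
                 loq_cv_threshold = loq_cv_threshold,
                 inhibition_threshold = inhibition_threshold,
                 negative_fill = match.arg(negative_fill),
                 p_adjust = match.arg(p_adjust),
                 clip_negative_delta = clip_negative_delta,
                 lod_method = match.arg(lod_method),
                 seed = seed),
            class = "pipeline_config")
}

#' Write a pipeline configuration to JSON
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$volumes <- unclass(x$volumes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' Round-trips with [write_config()]: a written configuration parses back
#' identically.
#'
#' @param path JSON path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    volumes = do.call(volume_config, as.list(x$volumes)),
    lod_probability = x$lod_probability,
    loq_cv_threshold = x$loq_cv_threshold,
    inhibition_threshold = x$inhibition_threshold,
    negative_fill = x$negative_fill,
    p_adjust = x$p_adjust,
    clip_negative_delta = x$clip_negative_delta,
    lod_method = x$lod_method,
    seed = x$seed)
}
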