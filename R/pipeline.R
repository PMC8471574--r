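stage_try <- function(stage, assay, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed%s: %s", stage,
                 if (is.null(assay)) "" else paste0(" for assay '", assay, "'"),
                 conditionMessage(e)), call. = FALSE)
  })
}

# cheap deterministic checksum of the configuration, recorded in the run log
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

#' Run the full eDNA qPCR quantification pipeline
#'
#' Fixed stage order over a combined plate table: calibrate each assay's
#' standard curve, estimate its LOD/LOQ, compute inhibition delays from the
#' IPC wells, back-calculate and inhibition-normalize the unknown
#' reactions, gate them against LOD/LOQ, convert to copies per liter with
#' the log10(x + 1) transform, summarize by group, and run the rank-based
#' comparison families. Normalization precedes gating, so detection calls
#' are made on inhibition-corrected copy numbers.
#'
#' @param plate Combined plate data frame: `standard` and `unknown` rows
#'   per assay, plus `ipc_control`/`ipc_sample` wells and `ntc` controls.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all artifacts are written
#'   there (calibration.json, sensitivity.json, inhibition.tsv,
#'   quantified.tsv, comparisons.tsv, run_log.txt).
#' @param ipc_assay Name of the IPC assay in the `assay` column.
#' @return Invisibly, a list with `calibration`, `sensitivity` (per-assay
#'   lists), `inhibition`, `quantified`, `site_summary`, `group_means`,
#'   `comparisons`.
#' @export
run_pipeline <- function(plate, config = pipeline_config(), out_dir = NULL,
                         ipc_assay = "IPC") {
  stopifnot(is.data.frame(plate), inherits(config, "pipeline_config"))
  check_ipc_controls(plate, ipc_assay = ipc_assay)
  assays <- setdiff(unique(plate$assay[plate$reaction_type %in%
                                         c("standard", "unknown")]),
                    ipc_assay)
  if (length(assays) == 0L) stop("no species assays on the plate", call. = FALSE)

  calibration <- list()
  sensitivity <- list()
  for (a in assays) {
    std <- plate[plate$assay == a & plate$reaction_type == "standard", ,
                 drop = FALSE]
    calibration[[a]] <- stage_try("calibration", a, {
      if (nrow(std) == 0L) stop("no standards on the plate")
      fit_standard_curve(std)
    })
    sensitivity[[a]] <- stage_try("sensitivity", a, estimate_sensitivity(
      std, curve = calibration[[a]],
      probability = config$lod_probability,
      cv_threshold = config$loq_cv_threshold,
      lod_method = config$lod_method))
  }

  has_ipc <- any(plate$reaction_type == "ipc_sample")
  inhibition <- if (has_ipc) {
    stage_try("inhibition", NULL, inhibition_table(
      plate, by = c("site", "season"),
      threshold = config$inhibition_threshold))
  } else NULL

  quantified <- do.call(rbind, lapply(assays, function(a)
    stage_try("quantification", a, quantify_survey(
      plate, calibration[[a]], sensitivity[[a]], inhibition,
      volumes = config$volumes, assay = a,
      clip_negative_delta = config$clip_negative_delta))))

  site_summary <- stage_try("summary", NULL, summarize_survey(
    quantified, group_keys = intersect(c("assay", "site", "season"),
                                       names(quantified)),
    negative_fill = config$negative_fill))

  group_means <- if ("season" %in% names(quantified)) {
    gm <- stage_try("summary", NULL, summarize_survey(
      quantified, group_keys = c("assay", "season"),
      negative_fill = config$negative_fill))
    seasons <- unique(gm$season)
    if (length(seasons) == 2L) {
      fc <- vapply(unique(gm$assay), function(a) {
        m <- gm[gm$assay == a, ]
        m1 <- m$mean_copies_per_liter[m$season == seasons[1L]]
        m2 <- m$mean_copies_per_liter[m$season == seasons[2L]]
        if (length(m1) == 1L && length(m2) == 1L && m2 > 0) m1 / m2 else NA_real_
      }, numeric(1))
      attr(gm, "fold_change") <- data.frame(
        assay = unique(gm$assay),
        numerator = seasons[1L], denominator = seasons[2L],
        fold_change = unname(fc))
    }
    gm
  } else NULL

  comparisons <- if ("season" %in% names(quantified) &&
                     (length(assays) >= 2L ||
                        length(unique(quantified$season)) >= 2L)) {
    stage_try("comparison", NULL,
              compare_groups(quantified, adjust = config$p_adjust))
  } else NULL

  result <- list(calibration = calibration, sensitivity = sensitivity,
                 inhibition = inhibition, quantified = quantified,
                 site_summary = site_summary, group_means = group_means,
                 comparisons = comparisons)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, config, out_dir)
  invisible(result)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  path
}

#' Write the pipeline's report bundle
#'
#' Serializes a [run_pipeline()] result: per-assay calibration and
#' sensitivity JSON reports, the inhibition/quantified/comparisons TSVs,
#' site and group summaries, and a run log with package version, seed and
#' configuration hash. Outputs are deterministic: re-running the pipeline
#' on the same plate with the same configuration reproduces the files
#' byte for byte.
#'
#' @param result [run_pipeline()] return value.
#' @param config The [pipeline_config()] used.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  written <- character(0)

  cal <- lapply(result$calibration, function(x) {
    list(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         efficiency_pct = x$efficiency_pct, n_points = x$n_points,
         copies_range = x$copies_range, warnings = x$warnings)
  })
  jsonlite::write_json(cal, p("calibration.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, p("calibration.json"))

  sens <- lapply(result$sensitivity, function(x) {
    list(lod_copies = x$lod_copies, loq_copies = x$loq_copies,
         lod_model = x$lod_model, loq_model = x$loq_model,
         lod_censored = x$lod_censored, loq_censored = x$loq_censored,
         probability = x$probability, cv_threshold = x$cv_threshold,
         fit_diagnostics = x$fit_diagnostics, notes = x$notes)
  })
  jsonlite::write_json(sens, p("sensitivity.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, p("sensitivity.json"))

  if (!is.null(result$inhibition))
    written <- c(written, write_tsv(result$inhibition, p("inhibition.tsv")))
  written <- c(written, write_tsv(result$quantified, p("quantified.tsv")))
  written <- c(written, write_tsv(result$site_summary, p("site_summary.tsv")))
  if (!is.null(result$comparisons))
    written <- c(written, write_tsv(result$comparisons, p("comparisons.tsv")))
  if (!is.null(result$group_means)) {
    gm <- list(group_means = result$group_means,
               fold_change = attr(result$group_means, "fold_change"))
    jsonlite::write_json(gm, p("group_means.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, p("group_means.json"))
  }

  log_lines <- c(
    sprintf("ednaqpcr %s",
            as.character(utils::packageVersion("ednaqpcr"))),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
    sprintf("config hash: %s", config_hash(config)),
    sprintf("assays: %s", paste(names(result$calibration), collapse = ", ")),
    sprintf("reactions quantified: %d", nrow(result$quantified)))
  writeLines(log_lines, p("run_log.txt"))
  written <- c(written, p("run_log.txt"))
  invisible(written)
}

#' Reference sensitivity panel for the four salmon assays
#'
#' The published per-assay sensitivity and efficiency of the four
#' Oncorhynchus TaqMan assays (chum, coho, masu, steelhead): LOD and LOQ in
#' copies per reaction and amplification efficiency in percent. Shipped as
#' a plain-text table and used by the reporting helpers.
#'
#' @return Data frame with `species`, `lod_copies`, `loq_copies`,
#'   `efficiency_pct`.
#' @export
reference_assay_panel <- function() {
  path <- system.file("extdata", "assay_sensitivity_reference.tsv",
                      package = "ednaqpcr", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Summarize an assay sensitivity panel
#'
#' Reporting helper: panel-level mean LOD and LOQ and the efficiency
#' range. Means are reported unrounded; report formatting decides the
#' printed precision.
#'
#' @param panel A data frame like [reference_assay_panel()].
#' @return List with `mean_lod`, `mean_loq`, `efficiency_range`, `n_assays`.
#' @export
assay_panel_summary <- function(panel = reference_assay_panel()) {
  stopifnot(all(c("lod_copies", "loq_copies") %in% names(panel)))
  list(mean_lod = mean(panel$lod_copies),
       mean_loq = mean(panel$loq_copies),
       efficiency_range = if ("efficiency_pct" %in% names(panel))
         range(panel$efficiency_pct) else NULL,
       n_assays = nrow(panel))
}
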