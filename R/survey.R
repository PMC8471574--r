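#' Three-way detection gating of a reaction
#'
#' Classifies an inhibition-normalized copy number against the assay's LOD
#' and LOQ: `negative` when copies are at or below the LOD (including
#' non-detects, which carry zero copies), `detected_below_loq` when between
#' LOD and LOQ (a detection, but too imprecise to quantify), and
#' `quantifiable` at or above the LOQ.
#'
#' @param normalized_copies Copies per reaction after inhibition
#'   normalization; `NA` (no valid estimate) maps to `NA` status.
#' @param lod,loq Assay detection and quantification limits,
#'   copies/reaction; must satisfy `lod <= loq`.
#' @return Factor with levels `negative`, `detected_below_loq`,
#'   `quantifiable`.
#' @export
classify_detection <- function(normalized_copies, lod, loq) {
  if (!is.finite(lod) || !is.finite(loq))
    stop("configuration error: LOD and LOQ must be finite", call. = FALSE)
  if (lod > loq)
    stop("configuration error: lod > loq", call. = FALSE)
  lv <- c("negative", "detected_below_loq", "quantifiable")
  x <- ifelse(is.na(normalized_copies), NA_character_,
       ifelse(normalized_copies <= lod, "negative",
       ifelse(normalized_copies < loq, "detected_below_loq", "quantifiable")))
  factor(x, levels = lv)
}

#' Site-level detection call
#'
#' A site is scored as positive for a species when at least one replicate
#' reaction exceeds the LOD (any status other than `negative`).
#'
#' @param statuses Statuses of a site's replicates ([classify_detection()]
#'   output or the corresponding strings).
#' @return Logical scalar.
#' @export
site_detection <- function(statuses) {
  statuses <- statuses[!is.na(statuses)]
  if (length(statuses) == 0L) stop("no replicate statuses", call. = FALSE)
  any(as.character(statuses) != "negative")
}

#' Convert copies per reaction to copies per liter of sampled water
#'
#' `copies_rxn * (elution_volume / template_volume) / filtration_volume`:
#' the reaction sees `template/elution` of the extract, which in turn
#' represents `filtration_volume` liters of water. With the default volumes
#' the factor is exactly 50.
#'
#' @param copies_rxn Copies per reaction, >= 0.
#' @param volumes A [volume_config()].
#' @return Copies per liter.
#' @export
copies_per_liter <- function(copies_rxn, volumes = volume_config()) {
  stopifnot(inherits(volumes, "volume_config"))
  if (any(copies_rxn < 0, na.rm = TRUE))
    stop("copies must be non-negative", call. = FALSE)
  copies_rxn * (volumes$elution_volume / volumes$template_volume) /
    volumes$filtration_volume
}

#' log10(x + 1) concentration transform
#'
#' Variance-stabilizing transform applied to copies per liter before
#' rank-based group comparisons and plotting; zero concentration maps to
#' zero.
#'
#' @param x Copies per liter, >= 0.
#' @return log10(x + 1).
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop("concentrations must be non-negative", call. = FALSE)
  log10(x + 1)
}

#' Ratio of two group mean concentrations
#'
#' Fold change of linear-scale mean concentrations, `mean_a / mean_b`.
#' A zero denominator has no defined ratio and returns `Inf` with a
#' warning (censored ratio).
#'
#' @param mean_a,mean_b Group mean concentrations (copies/L).
#' @return The ratio.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_b == 0)) {
    warning("zero denominator: fold change undefined (censored)",
            call. = FALSE)
    return(ifelse(mean_b == 0, Inf, mean_a / mean_b))
  }
  mean_a / mean_b
}

#' Quantify field reactions through the full per-reaction pipeline
#'
#' For every `unknown` reaction of one assay: back-calculate raw copies from
#' Cq through the standard curve (non-detect = 0 copies), multiply by the
#' group's inhibition correction factor 2^delta_cq, gate the normalized
#' copies by LOD/LOQ, convert to copies per liter and apply the
#' log10(x + 1) transform. Samples whose IPC did not amplify have no finite
#' correction; their reactions are excluded from quantification (status
#' `NA`) with a warning.
#'
#' @param plate Plate data frame (one assay's `unknown` rows are used).
#' @param curve `standard_curve` for the assay.
#' @param sensitivity `sensitivity_result` for the assay.
#' @param inhibition Output of [inhibition_table()]; joined on its grouping
#'   columns. Omit (`NULL`) to skip normalization (delta_cq = 0).
#' @param volumes A [volume_config()].
#' @param assay Assay name to select; defaults to the single assay present.
#' @param clip_negative_delta Passed to [normalize_copies()].
#' @return Data frame, one row per reaction: identifiers, `cq`,
#'   `raw_copies`, `delta_cq`, `normalized_copies`, `status`,
#'   `copies_per_liter`, `log_copies`.
#' @export
quantify_survey <- function(plate, curve, sensitivity, inhibition = NULL,
                            volumes = volume_config(), assay = NULL,
                            clip_negative_delta = FALSE) {
  stopifnot(inherits(curve, "standard_curve"),
            inherits(sensitivity, "sensitivity_result"))
  unk <- plate[plate$reaction_type == "unknown", , drop = FALSE]
  if (!is.null(assay)) unk <- unk[unk$assay == assay, , drop = FALSE]
  if (nrow(unk) == 0L) stop("no unknown reactions to quantify", call. = FALSE)
  if (length(unique(unk$assay)) > 1L)
    stop("multiple assays present; pass `assay`", call. = FALSE)

  unk$raw_copies <- ifelse(is.na(unk$cq), 0, cq_to_copies(unk$cq, curve))
  if (is.null(inhibition)) {
    unk$delta_cq <- 0
  } else {
    by <- intersect(names(inhibition),
                    c("sample_id", "site", "season", "stream_class"))
    by <- intersect(by, names(unk))
    if (length(by) == 0L)
      stop("inhibition table shares no identifier columns with the plate",
           call. = FALSE)
    idx <- match(interaction(unk[by], drop = FALSE),
                 interaction(inhibition[by], drop = FALSE))
    if (any(is.na(idx)))
      stop("missing inhibition assay for ", sum(is.na(idx)), " reaction(s)",
           call. = FALSE)
    unk$delta_cq <- inhibition$delta_cq[idx]
  }

  unk$normalized_copies <- ifelse(
    is.finite(unk$delta_cq),
    normalize_copies(unk$raw_copies, unk$delta_cq,
                     clip_negative_delta = clip_negative_delta),
    NA_real_)
  if (any(!is.finite(unk$delta_cq)))
    warning(sum(!is.finite(unk$delta_cq)), " reaction(s) excluded: ",
            "non-amplified sample IPC leaves no finite correction",
            call. = FALSE)

  unk$status <- classify_detection(unk$normalized_copies,
                                   sensitivity$lod_copies,
                                   sensitivity$loq_copies)
  unk$copies_per_liter <- copies_per_liter(unk$normalized_copies, volumes)
  unk$log_copies <- log_transform(unk$copies_per_liter)
  keep <- intersect(c("sample_id", "site", "season", "stream_class",
                      "replicate", "assay", "cq", "raw_copies", "delta_cq",
                      "normalized_copies", "status", "copies_per_liter",
                      "log_copies"), names(unk))
  out <- unk[keep]
  rownames(out) <- NULL
  out
}

#' Group summaries of quantified survey reactions
#'
#' Aggregates quantified reactions by the requested keys. A group counts as
#' detected when any replicate exceeds the LOD. Group mean concentrations
#' are computed over quantifiable replicates plus -- under the default
#' `zero_fill` rule -- negative replicates entered as zero copies/L (a
#' detection failure is evidence of at-most-trace concentration); under
#' `omit`, only quantifiable replicates enter the mean. Detections below
#' the LOQ are always excluded from means (they carry no reliable copy
#' estimate) but count as detections.
#'
#' @param quantified Output of [quantify_survey()].
#' @param group_keys Grouping columns, e.g. `c("assay", "site", "season")`.
#' @param negative_fill `"zero_fill"` (default) or `"omit"`.
#' @return Data frame: grouping columns, `n_replicates`, `n_detected`,
#'   `n_quantifiable`, `detected`, `mean_copies_per_liter`,
#'   `mean_log_copies`.
#' @export
summarize_survey <- function(quantified,
                             group_keys = c("assay", "site", "season"),
                             negative_fill = c("zero_fill", "omit")) {
  negative_fill <- match.arg(negative_fill)
  missing_keys <- setdiff(group_keys, names(quantified))
  if (length(missing_keys) > 0L)
    stop("unknown group key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  q <- quantified[!is.na(quantified$status), , drop = FALSE]
  key <- interaction(q[group_keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(q, key), function(g) {
    st <- as.character(g$status)
    use <- if (negative_fill == "zero_fill") st != "detected_below_loq"
           else st == "quantifiable"
    vals <- ifelse(st == "negative", 0, g$copies_per_liter)[use]
    cbind(g[1L, group_keys, drop = FALSE],
          n_replicates = nrow(g),
          n_detected = sum(st != "negative"),
          n_quantifiable = sum(st == "quantifiable"),
          detected = site_detection(g$status),
          mean_copies_per_liter = if (length(vals)) mean(vals) else 0,
          mean_log_copies = if (length(vals)) mean(log_transform(vals)) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
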