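#' PCR inhibition from an internal positive control (IPC) pair
#'
#' The delay of the IPC quantification cycle in an environmental extract
#' relative to a clean control reaction: `delta_cq = cq_sample - cq_control`
#' (positive = delayed = inhibited). The implied copy-number correction
#' factor is `2^delta_cq`, and a delay of more than `threshold` cycles
#' (default 3, roughly a 10-fold underestimation) is flagged as significant
#' inhibition. A non-amplified sample IPC (`cq_sample = NA`) has no finite
#' correction; it is reported as `delta_cq = Inf` and flagged significant.
#'
#' @param cq_sample IPC Cq in the eDNA extract; `NA` = non-amplified.
#' @param cq_control IPC Cq in the clean control reaction.
#' @param threshold Significance threshold in cycles.
#' @return Data frame with `cq_control`, `cq_sample`, `delta_cq`, `factor`
#'   (= 2^delta_cq) and `significant` (vectorized over inputs).
#' @examples
#' compute_inhibition(29.33, 28)   # delta 1.33, factor 2.51
#' @export
compute_inhibition <- function(cq_sample, cq_control, threshold = 3) {
  if (any(is.na(cq_control)))
    stop("assay invalid: missing control Cq", call. = FALSE)
  stopifnot(is.numeric(cq_control), threshold > 0)
  delta <- ifelse(is.na(cq_sample), Inf, cq_sample - cq_control)
  data.frame(cq_control = cq_control,
             cq_sample = as.numeric(cq_sample),
             delta_cq = delta,
             factor = 2^delta,
             significant = delta > threshold)
}

#' Inhibition-normalize raw copy numbers
#'
#' Multiplies raw copies per reaction by the IPC-derived correction factor
#' `2^delta_cq`, inflating copies in inhibited samples back toward their
#' uninhibited value. Negative delays (apparent facilitation) shrink copies
#' unless `clip_negative_delta` is set, in which case they are treated as
#' zero delay.
#'
#' @param raw_copies Raw copies per reaction, >= 0.
#' @param delta_cq Inhibition delay in cycles.
#' @param clip_negative_delta Clip negative delays to 0 before correcting.
#' @return Normalized copies per reaction.
#' @export
normalize_copies <- function(raw_copies, delta_cq, clip_negative_delta = FALSE) {
  if (any(raw_copies < 0, na.rm = TRUE))
    stop("raw_copies must be non-negative", call. = FALSE)
  if (clip_negative_delta) delta_cq <- pmax(delta_cq, 0)
  raw_copies * 2^delta_cq
}

#' Validate IPC no-template controls
#'
#' IPC reactions run without the IPC template must not amplify; any
#' amplification there indicates cross-reactivity of the IPC primers with
#' the environmental extract (or contamination) and invalidates the
#' inhibition assay. Checks `ntc` rows of the IPC assay in a plate table.
#'
#' @param plate Plate data frame.
#' @param ipc_assay Name of the IPC assay in the `assay` column.
#' @return Invisibly `TRUE`; errors when an IPC NTC well amplified.
#' @export
check_ipc_controls <- function(plate, ipc_assay = "IPC") {
  ntc <- plate[plate$reaction_type == "ntc" & plate$assay == ipc_assay, ,
               drop = FALSE]
  if (nrow(ntc) > 0L && any(!is.na(ntc$cq)))
    stop("IPC cross-reactivity: ", sum(!is.na(ntc$cq)),
         " no-template IPC well(s) amplified", call. = FALSE)
  invisible(TRUE)
}

#' Per-group inhibition table from IPC plate wells
#'
#' Pairs the plate's `ipc_sample` wells (IPC spiked into each eDNA extract)
#' with its `ipc_control` wells (IPC in clean reactions) and reports the
#' inhibition delay per group. The control Cq is the mean over all
#' `ipc_control` wells on the plate; the sample Cq is averaged over each
#' group's replicate wells (any non-amplified well makes the group's delay
#' infinite, since no finite correction exists). Grouping defaults to
#' site x season, matching how field samples are normalized.
#'
#' @param plate Plate data frame containing `ipc_control` and `ipc_sample`
#'   rows.
#' @param by Grouping columns among the plate's identifier columns.
#' @param threshold Significance threshold in cycles.
#' @return Data frame: grouping columns, `n_wells`, `cq_control`,
#'   `cq_sample`, `delta_cq`, `factor`, `significant`.
#' @export
inhibition_table <- function(plate, by = c("site", "season"), threshold = 3) {
  ctrl <- plate[plate$reaction_type == "ipc_control", , drop = FALSE]
  samp <- plate[plate$reaction_type == "ipc_sample", , drop = FALSE]
  if (nrow(ctrl) == 0L)
    stop("assay invalid: no ipc_control wells on the plate", call. = FALSE)
  if (nrow(samp) == 0L)
    stop("no ipc_sample wells on the plate", call. = FALSE)
  if (any(is.na(ctrl$cq)))
    stop("assay invalid: non-amplified ipc_control well", call. = FALSE)
  by <- intersect(by, names(samp))
  if (length(by) == 0L) stop("no valid grouping columns", call. = FALSE)
  cq_control <- mean(ctrl$cq)

  key <- interaction(samp[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(samp, key), function(g) {
    cq_sample <- if (any(is.na(g$cq))) NA_real_ else mean(g$cq)
    cbind(g[1L, by, drop = FALSE],
          n_wells = nrow(g),
          compute_inhibition(cq_sample, cq_control, threshold = threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seasonal summary of inhibition delays
#'
#' Mean, standard deviation and range of finite inhibition delays per
#' season, the summary used to compare inhibition between sampling events.
#'
#' @param inhibition Output of [inhibition_table()] with a `season` column.
#' @return Data frame per season: `n`, `mean_delta`, `sd_delta`,
#'   `min_delta`, `max_delta`.
#' @export
inhibition_summary <- function(inhibition) {
  stopifnot("season" %in% names(inhibition))
  fin <- inhibition[is.finite(inhibition$delta_cq), , drop = FALSE]
  rows <- lapply(split(fin, fin$season), function(g) {
    data.frame(season = g$season[1L], n = nrow(g),
               mean_delta = mean(g$delta_cq),
               sd_delta = stats::sd(g$delta_cq),
               min_delta = min(g$delta_cq),
               max_delta = max(g$delta_cq))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
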