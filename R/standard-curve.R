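#' Volume configuration for copies-per-liter conversion
#'
#' Collects the three volumes that link copies per qPCR reaction to copies
#' per liter of sampled water: the template volume pipetted into the
#' reaction, the elution volume of the DNA extraction, and the volume of
#' water pushed through the filter. With the defaults (2 uL template, 50 uL
#' elution, 0.5 L filtered) one copy per reaction corresponds to 50 copies
#' per liter.
#'
#' @param template_volume Template volume per reaction, in microliters.
#' @param elution_volume Final elution volume of the extraction, in
#'   microliters.
#' @param filtration_volume Water volume filtered per sub-sample, in liters.
#' @return An object of class `volume_config`.
#' @examples
#' v <- volume_config()
#' copies_per_liter(100, v)  # 5000
#' @export
volume_config <- function(template_volume = 2, elution_volume = 50,
                          filtration_volume = 0.5) {
  stopifnot(is.numeric(template_volume), is.numeric(elution_volume),
            is.numeric(filtration_volume))
  if (template_volume <= 0 || elution_volume <= 0 || filtration_volume <= 0)
    stop("all volumes must be strictly positive", call. = FALSE)
  if (template_volume > elution_volume)
    stop("template_volume cannot exceed elution_volume", call. = FALSE)
  structure(list(template_volume = template_volume,
                 elution_volume = elution_volume,
                 filtration_volume = filtration_volume),
            class = "volume_config")
}

#' Amplification efficiency from a standard-curve slope
#'
#' The per-cycle amplification gain implied by the calibration slope,
#' E = (10^(-1/slope) - 1) * 100. A slope of -1/log10(2) = -3.3219 cycles
#' per decade corresponds to perfect doubling (100%).
#'
#' @param slope Standard-curve slope in cycles per log10(copies); must be
#'   negative.
#' @return Efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  stopifnot(is.numeric(slope))
  if (any(!is.finite(slope)) || any(slope >= 0))
    stop("slope must be finite and negative", call. = FALSE)
  (10^(-1 / slope) - 1) * 100
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Ordinary least-squares regression of Cq on log10(known copies) over the
#' detected standard reactions. Non-detects (missing Cq) are excluded from
#' the fit; they carry no Cq and imputing one at the cycle limit would bias
#' the slope. Amplification efficiency outside the conventional 90--110%
#' acceptance window is recorded as a warning flag, not an error.
#'
#' @param standards A data frame of standard reactions with columns
#'   `known_copies` (copies per reaction) and `cq` (quantification cycle;
#'   `NA` = non-detect). Rows with a `reaction_type` column are filtered to
#'   `reaction_type == "standard"` first.
#' @param efficiency_range Acceptance window for efficiency, in percent.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency_pct`, `n_points`, `copies_range`
#'   (range of detected standards) and `warnings`.
#' @examples
#' std <- data.frame(known_copies = rep(10^(1:5), each = 3))
#' std$cq <- 38 - 3.321928 * log10(std$known_copies)
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards, efficiency_range = c(90, 110)) {
  stopifnot(is.data.frame(standards))
  if (!is.null(standards$reaction_type))
    standards <- standards[standards$reaction_type == "standard", , drop = FALSE]
  if (!all(c("known_copies", "cq") %in% names(standards)))
    stop("standards need 'known_copies' and 'cq' columns", call. = FALSE)
  det <- standards[!is.na(standards$cq), , drop = FALSE]
  if (nrow(det) == 0L)
    stop("calibration error: all standard reactions are non-detects",
         call. = FALSE)
  if (any(det$known_copies <= 0))
    stop("known_copies must be strictly positive", call. = FALSE)
  if (length(unique(det$known_copies)) < 3L)
    stop("calibration error: need >= 3 distinct standard concentrations with ",
         "detected Cq", call. = FALSE)

  fit <- stats::lm(cq ~ log10(known_copies), data = det)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope >= 0)
    stop("calibration error: fitted slope is not negative; Cq must decrease ",
         "with template copies", call. = FALSE)
  eff <- efficiency_from_slope(slope)
  warnings <- character(0)
  if (eff < efficiency_range[1] || eff > efficiency_range[2])
    warnings <- c(warnings, sprintf(
      "efficiency %.2f%% outside accepted range [%g, %g]%%",
      eff, efficiency_range[1], efficiency_range[2]))

  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((det$cq - mean(det$cq))^2)
  structure(list(
    slope = slope,
    intercept = intercept,
    r_squared = if (tss > 0) 1 - rss / tss else 1,
    efficiency_pct = eff,
    n_points = nrow(det),
    copies_range = range(det$known_copies),
    warnings = warnings
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  Cq = %.4f %+.4f * log10(copies)\n", x$intercept, x$slope))
  cat(sprintf("  efficiency %.2f%%, r^2 = %.4f, n = %d (copies %g..%g)\n",
              x$efficiency_pct, x$r_squared, x$n_points,
              x$copies_range[1], x$copies_range[2]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Back-calculate template copies from a Cq value
#'
#' Inverts the calibration line: copies = 10^((cq - intercept) / slope).
#' Extrapolation outside the fitted standards' range is permitted -- field
#' samples routinely fall below the lowest standard -- and flagged with a
#' warning when `warn_extrapolation` is on.
#'
#' @param cq Quantification cycle(s); `NA` (non-detect) maps to `NA`.
#' @param curve A `standard_curve`.
#' @param warn_extrapolation Warn when a Cq maps outside the standards'
#'   concentration range.
#' @return Copies per reaction (vectorized).
#' @export
cq_to_copies <- function(cq, curve, warn_extrapolation = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((cq - curve$intercept) / curve$slope)
  if (warn_extrapolation) {
    out <- !is.na(copies) &
      (copies < curve$copies_range[1] | copies > curve$copies_range[2])
    if (any(out))
      warning(sum(out), " value(s) back-calculated outside the standards' ",
              "range (extrapolation)", call. = FALSE)
  }
  copies
}

#' Expected Cq for a given template copy number
#'
#' Forward evaluation of the calibration line; exact inverse of
#' [cq_to_copies()].
#'
#' @param copies Copies per reaction, > 0.
#' @param curve A `standard_curve`.
#' @return Cq value(s).
#' @export
copies_to_cq <- function(copies, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(copies <= 0, na.rm = TRUE))
    stop("copies must be strictly positive", call. = FALSE)
  curve$intercept + curve$slope * log10(copies)
}

#' Convert plasmid mass to copy number
#'
#' Copies = mass[g] * N_A / (length * 660 g/mol/bp), using the average
#' molar mass of a double-stranded base pair. Useful to express standards
#' prepared gravimetrically (nanograms of plasmid) in copies per reaction;
#' `construct_length` is the total length of vector plus insert.
#'
#' @param mass_ng Mass in nanograms, >= 0.
#' @param construct_length Construct length in base pairs, > 0.
#' @return Copy number.
#' @examples
#' ng_to_copies(1, 3000)  # ~3.04e8
#' @export
ng_to_copies <- function(mass_ng, construct_length) {
  stopifnot(is.numeric(mass_ng), is.numeric(construct_length))
  if (any(mass_ng < 0)) stop("mass must be non-negative", call. = FALSE)
  if (any(construct_length <= 0))
    stop("construct length must be positive", call. = FALSE)
  avogadro <- 6.02214076e23
  mass_ng * 1e-9 * avogadro / (construct_length * 660)
}
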