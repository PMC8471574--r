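#' Per-concentration detection summary of a dilution series
#'
#' Collapses replicated standard reactions into one row per concentration
#' with replicate and detection counts, the input to LOD estimation.
#' Non-detects count toward `n_replicates` only.
#'
#' @param standards Data frame of standard reactions (`known_copies`, `cq`;
#'   `NA` Cq = non-detect). A `reaction_type` column, if present, is
#'   filtered to `"standard"`.
#' @return Data frame with columns `copies`, `n_replicates`, `n_detected`,
#'   `p_detected`, ordered by increasing concentration.
#' @export
summarize_detections <- function(standards) {
  stopifnot(is.data.frame(standards))
  if (!is.null(standards$reaction_type))
    standards <- standards[standards$reaction_type == "standard", , drop = FALSE]
  if (nrow(standards) == 0L) stop("no standard reactions", call. = FALSE)
  agg <- stats::aggregate(cbind(n_replicates = !is.na(known_copies),
                                n_detected = !is.na(cq)) ~ known_copies,
                          data = standards, FUN = sum, na.action = stats::na.pass)
  out <- data.frame(copies = agg$known_copies,
                    n_replicates = as.integer(agg$n_replicates),
                    n_detected = as.integer(agg$n_detected))
  out <- out[order(out$copies), , drop = FALSE]
  out$p_detected <- out$n_detected / out$n_replicates
  rownames(out) <- NULL
  out
}

# Binomial GLM fits for the two candidate detection-probability models.
# Poisson/cloglog: p(Q) = 1 - exp(-c Q), i.e. an intercept-only cloglog GLM
# with offset log(Q); the single-hit model where every reaction containing
# at least one amplifiable template (Poisson-distributed) is detected.
# Logistic: p as a logit-linear function of log10(Q).
fit_lod_model <- function(det, model) {
  resp <- cbind(det$n_detected, det$n_replicates - det$n_detected)
  fit <- tryCatch(suppressWarnings(switch(
    model,
    poisson_cloglog = stats::glm(
      resp ~ 1 + offset(log(det$copies)),
      family = stats::binomial(link = "cloglog")),
    logistic_log10 = stats::glm(
      resp ~ log10(det$copies),
      family = stats::binomial(link = "logit")),
    stop("unknown LOD model: ", model)
  )), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) return(NULL)
  # a non-increasing detection curve cannot define an LOD
  if (model == "logistic_log10" && cf[2L] <= 0) return(NULL)
  list(model = model, fit = fit, coef = cf, aic = stats::AIC(fit))
}

lod_predict <- function(m, copies) {
  switch(m$model,
    poisson_cloglog = 1 - exp(-exp(m$coef[1L]) * copies),
    logistic_log10 = stats::plogis(m$coef[1L] + m$coef[2L] * log10(copies)))
}

lod_solve <- function(m, probability) {
  switch(m$model,
    poisson_cloglog = -log(1 - probability) / exp(m$coef[1L]),
    logistic_log10 =
      10^((stats::qlogis(probability) - m$coef[1L]) / m$coef[2L]))
}

#' Estimate the limit of detection (LOD) from a dilution series
#'
#' Fits monotone detection-probability curves to per-concentration detection
#' counts by maximum binomial likelihood and solves for the concentration at
#' which the target detection probability (default 95%) is reached. Two
#' candidate curves are fitted -- a single-hit Poisson model
#' p(Q) = 1 - exp(-cQ) and a logistic curve in log10 copies -- and the one
#' with the lower AIC is used. When the fitted probability already meets the
#' target at the lowest tested concentration, that concentration is returned
#' with `censored = TRUE` (the true LOD lies at or below the tested range).
#' With `method = "discrete"` the model fit is skipped and the LOD is the
#' lowest concentration whose observed detection rate meets the target.
#'
#' @param detections Output of [summarize_detections()], or a raw standards
#'   data frame (summarized automatically).
#' @param probability Target detection probability (default 0.95).
#' @param method `"modeled"` (curve fit, default) or `"discrete"`.
#' @return List with `lod_copies`, `model`, `censored`, and `diagnostics`
#'   (per-candidate AIC).
#' @export
estimate_lod <- function(detections, probability = 0.95,
                         method = c("modeled", "discrete")) {
  method <- match.arg(method)
  stopifnot(probability > 0, probability < 1)
  if (!all(c("copies", "n_detected") %in% names(detections)))
    detections <- summarize_detections(detections)
  det <- detections[order(detections$copies), , drop = FALSE]
  det$p_detected <- det$n_detected / det$n_replicates
  if (all(det$n_detected == 0L))
    stop("LOD undefined: no concentration has any detection", call. = FALSE)

  if (method == "discrete") {
    ok <- det$copies[det$p_detected >= probability]
    if (length(ok) == 0L)
      return(list(lod_copies = max(det$copies), model = "discrete",
                  censored = TRUE, diagnostics = NULL))
    return(list(lod_copies = min(ok), model = "discrete",
                censored = min(ok) == min(det$copies), diagnostics = NULL))
  }

  cands <- Filter(Negate(is.null),
                  lapply(c("poisson_cloglog", "logistic_log10"),
                         function(m) fit_lod_model(det, m)))
  if (length(cands) == 0L)
    stop("LOD fit failed for all candidate models", call. = FALSE)
  aics <- vapply(cands, `[[`, numeric(1), "aic")
  best <- cands[[which.min(aics)]]
  diagnostics <- stats::setNames(aics, vapply(cands, `[[`, character(1), "model"))

  lowest <- min(det$copies)
  if (lod_predict(best, lowest) >= probability)
    return(list(lod_copies = lowest, model = best$model, censored = TRUE,
                diagnostics = diagnostics))
  lod <- unname(lod_solve(best, probability))
  list(lod_copies = lod, model = best$model, censored = FALSE,
       diagnostics = diagnostics)
}

#' Per-concentration coefficient of variation of back-calculated copies
#'
#' For each standard concentration with at least two detected replicates,
#' back-calculates copies per reaction through the standard curve and
#' reports the CV (sd/mean) among replicates. Non-detects carry no copy
#' estimate and are excluded; concentrations with fewer than two detected
#' replicates have no defined CV and are dropped.
#'
#' @param standards Standards data frame (`known_copies`, `cq`).
#' @param curve A `standard_curve` used for back-calculation.
#' @return Data frame with `copies`, `cv`, `n_used`.
#' @export
summarize_cv <- function(standards, curve) {
  stopifnot(is.data.frame(standards), inherits(curve, "standard_curve"))
  if (!is.null(standards$reaction_type))
    standards <- standards[standards$reaction_type == "standard", , drop = FALSE]
  det <- standards[!is.na(standards$cq), , drop = FALSE]
  if (nrow(det) == 0L) stop("no detected standard reactions", call. = FALSE)
  det$est <- cq_to_copies(det$cq, curve)
  rows <- lapply(split(det, det$known_copies), function(g) {
    if (nrow(g) < 2L) return(NULL)
    data.frame(copies = g$known_copies[1L],
               cv = stats::sd(g$est) / mean(g$est),
               n_used = nrow(g))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out) || nrow(out) == 0L)
    stop("CV undefined at every concentration (singleton replicates)",
         call. = FALSE)
  out <- out[order(out$copies), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gaussian least-squares AIC on a common footing for the three CV models;
# RSS is floored so that exact fits are compared by parameter count.
ls_aic <- function(rss, n, k) n * log(max(rss, 1e-12) / n) + 2 * k

fit_cv_model <- function(cvtab, model) {
  q <- cvtab$copies
  lq <- log10(q)
  cv <- cvtab$cv
  res <- tryCatch(switch(
    model,
    exponential_decay = {
      pos <- cv > 0
      if (sum(pos) < 2L) stop("too few positive CVs")
      start_fit <- stats::lm(log(cv[pos]) ~ q[pos])
      fit <- minpack.lm::nlsLM(
        cv ~ a * exp(-b * q),
        start = list(a = unname(exp(stats::coef(start_fit)[1L])),
                     b = unname(max(-stats::coef(start_fit)[2L], 1e-6))),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(predict = function(x) {
        cf <- stats::coef(fit)
        cf[["a"]] * exp(-cf[["b"]] * x)
      }, rss = sum(stats::residuals(fit)^2), k = 2L)
    },
    linear = {
      fit <- stats::lm(cv ~ lq)
      list(predict = function(x) {
        cf <- stats::coef(fit)
        cf[1L] + cf[2L] * log10(x)
      }, rss = sum(stats::residuals(fit)^2), k = 2L)
    },
    polynomial2 = {
      if (length(unique(lq)) < 3L) stop("too few levels for a quadratic")
      fit <- stats::lm(cv ~ lq + I(lq^2))
      list(predict = function(x) {
        cf <- stats::coef(fit)
        cf[1L] + cf[2L] * log10(x) + cf[3L] * log10(x)^2
      }, rss = sum(stats::residuals(fit)^2), k = 3L)
    },
    stop("unknown CV model: ", model)
  ), error = function(e) NULL)
  if (is.null(res)) return(NULL)
  res$model <- model
  res$aic <- ls_aic(res$rss, nrow(cvtab), res$k)
  res
}

# first concentration, scanning up from lo, at which f(q) <= threshold;
# refined by bisection on the bracketing interval (the fitted curve may be
# non-monotone under the quadratic model, so the scan finds the first
# crossing from above rather than assuming monotonicity)
first_crossing <- function(f, lo, hi, threshold, n_grid = 512L) {
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  vals <- f(grid)
  below <- which(vals <= threshold)
  if (length(below) == 0L) return(NULL)
  i <- below[1L]
  if (i == 1L) return(lo)
  a <- grid[i - 1L]; b <- grid[i]
  for (iter in 1:60) {
    mid <- sqrt(a * b)
    if (f(mid) <= threshold) b <- mid else a <- mid
  }
  b
}

#' Estimate the limit of quantification (LOQ) from a dilution series
#'
#' Models the replicate-to-replicate coefficient of variation of
#' back-calculated copy numbers as a function of template concentration and
#' reports the smallest concentration at which the fitted CV first drops to
#' the quantification threshold (default 35%). Three candidate curves are
#' fitted -- exponential decay in copies, linear in log10 copies, and
#' quadratic in log10 copies -- and compared by least-squares AIC. If the
#' fitted CV is already at or below threshold at the lowest standard the LOQ
#' is censored there; if the curve never reaches the threshold within the
#' standards' range the highest standard is returned, censored, with a
#' warning.
#'
#' @param standards Standards data frame (`known_copies`, `cq`).
#' @param curve A `standard_curve` for back-calculation.
#' @param cv_threshold Quantification CV threshold (default 0.35).
#' @return List with `loq_copies`, `model`, `censored`, `cv_table`, and
#'   `diagnostics` (per-candidate AIC).
#' @export
estimate_loq <- function(standards, curve, cv_threshold = 0.35) {
  stopifnot(cv_threshold > 0)
  cvtab <- summarize_cv(standards, curve)
  if (nrow(cvtab) < 3L)
    stop("need >= 3 concentrations with a defined CV", call. = FALSE)

  cands <- Filter(Negate(is.null),
                  lapply(c("exponential_decay", "linear", "polynomial2"),
                         function(m) fit_cv_model(cvtab, m)))
  if (length(cands) == 0L)
    stop("LOQ fit failed for all candidate CV models", call. = FALSE)
  aics <- vapply(cands, `[[`, numeric(1), "aic")
  best <- cands[[which.min(aics)]]
  diagnostics <- stats::setNames(aics, vapply(cands, `[[`, character(1), "model"))

  lo <- min(cvtab$copies); hi <- max(cvtab$copies)
  if (best$predict(lo) <= cv_threshold)
    return(list(loq_copies = lo, model = best$model, censored = TRUE,
                cv_table = cvtab, diagnostics = diagnostics))
  crossing <- first_crossing(best$predict, lo, hi, cv_threshold)
  if (is.null(crossing)) {
    warning("fitted CV never reaches the threshold within the standards' ",
            "range; LOQ censored at the highest standard", call. = FALSE)
    return(list(loq_copies = hi, model = best$model, censored = TRUE,
                cv_table = cvtab, diagnostics = diagnostics))
  }
  list(loq_copies = crossing, model = best$model, censored = FALSE,
       cv_table = cvtab, diagnostics = diagnostics)
}

#' Joint assay sensitivity: LOD and LOQ
#'
#' Runs [estimate_lod()] and [estimate_loq()] on the same dilution series
#' and enforces the ordering LOD <= LOQ (quantification can never be more
#' sensitive than detection): when the raw fits disagree, the reported LOQ
#' is raised to the LOD and a diagnostic note is attached.
#'
#' @param standards Standards data frame.
#' @param curve Optional `standard_curve`; fitted from `standards` when
#'   omitted.
#' @param probability LOD detection-probability target.
#' @param cv_threshold LOQ CV threshold.
#' @param lod_method Passed to [estimate_lod()].
#' @return An object of class `sensitivity_result`.
#' @export
estimate_sensitivity <- function(standards, curve = NULL, probability = 0.95,
                                 cv_threshold = 0.35,
                                 lod_method = "modeled") {
  if (is.null(curve)) curve <- fit_standard_curve(standards)
  lod <- estimate_lod(standards, probability = probability, method = lod_method)
  loq <- estimate_loq(standards, curve, cv_threshold = cv_threshold)
  notes <- character(0)
  loq_copies <- loq$loq_copies
  if (loq_copies < lod$lod_copies) {
    notes <- c(notes, sprintf(
      "fitted LOQ (%.3g) below LOD (%.3g); LOQ raised to LOD",
      loq_copies, lod$lod_copies))
    loq_copies <- lod$lod_copies
  }
  structure(list(
    lod_copies = lod$lod_copies, loq_copies = loq_copies,
    lod_model = lod$model, loq_model = loq$model,
    lod_censored = lod$censored, loq_censored = loq$censored,
    probability = probability, cv_threshold = cv_threshold,
    fit_diagnostics = list(lod = lod$diagnostics, loq = loq$diagnostics),
    cv_table = loq$cv_table, notes = notes
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Assay sensitivity\n")
  cat(sprintf("  LOD %.3g copies/reaction (%s%s) at %.0f%% detection\n",
              x$lod_copies, x$lod_model,
              if (x$lod_censored) ", censored" else "", 100 * x$probability))
  cat(sprintf("  LOQ %.3g copies/reaction (%s%s) at %.0f%% CV\n",
              x$loq_copies, x$loq_model,
              if (x$loq_censored) ", censored" else "", 100 * x$cv_threshold))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
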