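#' Significance stars for a p-value
#'
#' Conventional star coding: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p P-value(s) in \[0, 1\].
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

comparison_row <- function(group_a, group_b, method, statistic, p_raw,
                           p_adjusted = p_raw) {
  data.frame(group_a = group_a, group_b = group_b, method = method,
             statistic = statistic, p_raw = p_raw, p_adjusted = p_adjusted,
             stars = p_stars(p_adjusted), stringsAsFactors = FALSE)
}

#' Pairwise Wilcoxon rank-sum tests across groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) tests on every unordered pair
#' of groups, with the exact null distribution when both groups have at
#' most 10 observations and no ties are present, and the normal
#' approximation with tie and continuity correction otherwise. P-values are
#' adjusted across the whole pairwise family (Holm by default). The test is
#' rank-based, so results are identical whether values are raw
#' concentrations or their log10(x + 1) transforms.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length as `values`; >= 2 non-empty
#'   groups.
#' @param adjust Multiplicity adjustment: `"holm"`, `"bonferroni"`, or
#'   `"none"`.
#' @return Data frame of comparison rows (`group_a`, `group_b`, `method`,
#'   `statistic` = Mann-Whitney W, `p_raw`, `p_adjusted`, `stars`).
#' @export
pairwise_wilcoxon <- function(values, groups,
                              adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 1L)) stop("every group needs observations", call. = FALSE)

  pairs <- utils::combn(lv, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[groups == pairs[1L, i]]
    b <- values[groups == pairs[2L, i]]
    exact <- length(a) <= 10L && length(b) <= 10L &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(
      a, b, alternative = "two.sided", exact = exact, correct = TRUE))
    comparison_row(pairs[1L, i], pairs[2L, i], "wilcoxon",
                   unname(wt$statistic), wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  out$stars <- p_stars(out$p_adjusted)
  out
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance (Welch) t-test, used to compare inhibition
#' delays between seasons. When both groups are constant with equal means
#' there is no evidence of a difference and p = 1 by convention.
#'
#' @param a,b Numeric vectors, each with >= 2 observations.
#' @return A one-row comparison data frame (statistic = t).
#' @export
two_sample_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 observations", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(comparison_row("a", "b", "t_test", 0, 1))
    return(comparison_row("a", "b", "t_test",
                          sign(mean(a) - mean(b)) * Inf, 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  comparison_row("a", "b", "t_test", unname(tt$statistic), tt$p.value)
}

#' Spearman rank correlation
#'
#' Spearman's rho on average ranks with a two-sided p-value: the exact
#' permutation distribution for n <= 8 without ties, the t-approximation
#' otherwise. Used to relate inhibition delays to salinity. Constant input
#' leaves rho undefined (`NA`).
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return A one-row comparison data frame (statistic = rho).
#' @export
spearman_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman's rho undefined", call. = FALSE)
    return(comparison_row("x", "y", "spearman", NA_real_, NA_real_))
  }
  exact <- length(x) <= 8L && !any(duplicated(x)) && !any(duplicated(y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided",
                                         exact = exact))
  comparison_row("x", "y", "spearman", unname(ct$estimate), ct$p.value)
}

#' Survey-level comparison families
#'
#' Runs the survey's standard rank-based comparison families on quantified
#' reactions (log10(x + 1) copies/L, negatives as zero, detections below
#' the LOQ excluded): species against species within each season, season
#' against season within each species, and mainstem against tributary
#' within each season and species (when `stream_class` is present). Each
#' family is adjusted separately.
#'
#' @param quantified Output of [quantify_survey()] (rows may span assays).
#' @param adjust Multiplicity adjustment per family.
#' @return Data frame of comparison rows with a `family` column.
#' @export
compare_groups <- function(quantified, adjust = "holm") {
  q <- quantified[!is.na(quantified$status) &
                    as.character(quantified$status) != "detected_below_loq", ,
                  drop = FALSE]
  q$value <- ifelse(as.character(q$status) == "negative", 0, q$log_copies)
  out <- list()

  if ("season" %in% names(q)) {
    for (s in unique(q$season)) {
      g <- q[q$season == s, , drop = FALSE]
      if (length(unique(g$assay)) >= 2L) {
        rows <- pairwise_wilcoxon(g$value, g$assay, adjust = adjust)
        rows$family <- paste0("species_within_", s)
        out[[length(out) + 1L]] <- rows
      }
    }
    for (a in unique(q$assay)) {
      g <- q[q$assay == a, , drop = FALSE]
      if (length(unique(g$season)) >= 2L) {
        rows <- pairwise_wilcoxon(g$value, g$season, adjust = adjust)
        rows$family <- paste0("season_within_", a)
        out[[length(out) + 1L]] <- rows
      }
    }
  }
  if (all(c("stream_class", "season") %in% names(q))) {
    for (s in unique(q$season)) for (a in unique(q$assay)) {
      g <- q[q$season == s & q$assay == a, , drop = FALSE]
      if (length(unique(g$stream_class)) >= 2L &&
          all(table(g$stream_class) >= 1L)) {
        rows <- pairwise_wilcoxon(g$value, g$stream_class, adjust = adjust)
        rows$family <- paste0("stream_class_", a, "_", s)
        out[[length(out) + 1L]] <- rows
      }
    }
  }
  if (length(out) == 0L) stop("nothing to compare", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
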