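# Independent oracles and fixture builders used across the suite.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# allocations of the pooled sample (valid without ties).
enumerate_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u_obs <- u_of(seq_len(n))
  us <- apply(utils::combn(length(pooled), n), 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Spearman's rho as Pearson correlation of average ranks.
rank_rho <- function(x, y) stats::cor(rank(x), rank(y))

# Noiseless dilution standards lying exactly on a calibration line.
noiseless_standards <- function(slope, intercept, copies = 10^(1:7),
                                reps = 3L) {
  std <- data.frame(known_copies = rep(copies, each = reps))
  std$cq <- intercept + slope * log10(std$known_copies)
  std
}

# Standards engineered so the back-calculated copy CV at each level equals
# cv_fn(Q) exactly: two replicates at Q * (1 -+ d) with d = cv / sqrt(2)
# (sample sd of the pair is d * Q * sqrt(2)), mapped to Cq through the
# curve so back-calculation inverts exactly.
cv_standards <- function(curve, copies, cv_fn) {
  rows <- lapply(copies, function(q) {
    d <- cv_fn(q) / sqrt(2)
    est <- q * c(1 - d, 1 + d)
    data.frame(known_copies = q, cq = copies_to_cq(est, curve))
  })
  do.call(rbind, rows)
}

# A reference curve shared by fixtures.
fixture_curve <- function() {
  fit_standard_curve(noiseless_standards(-3.4149, 37.5))
}

# Detection summaries drawn from the single-hit Poisson detection model
# p(Q) = 1 - exp(-eff * Q).
poisson_detections <- function(copies, n, eff = 1) {
  data.frame(copies = copies, n_replicates = n,
             n_detected = stats::rbinom(length(copies), n,
                                        1 - exp(-eff * copies)),
             p_detected = NA_real_)
}
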