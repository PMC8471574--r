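---
title: "Methods: standardized eDNA qPCR quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized eDNA qPCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaqpcr)
```

## The problem

A species-specific eDNA qPCR survey asks two questions of every water
sample: is the target species' DNA present, and at what concentration?
Answering them comparably across sites, seasons and laboratories
requires an explicit chain of calibration and correction steps, because
raw Cq values confound template amount with assay efficiency, PCR
inhibition, and sampling volumes. This package implements that chain as
composable, tested functions; this vignette records the modelling
choices and their rationale.

## Calibration

`fit_standard_curve()` regresses Cq on log10 copies over the *detected*
standard reactions (ordinary least squares). Non-detects are excluded
rather than imputed at the cycle limit: a non-amplified well carries no
Cq, and any imputed value would drag the slope toward shallowness at the
low end. At least three distinct concentrations are required — with
fewer, slope and intercept are not separately identifiable in any useful
sense. Amplification efficiency is derived from the slope as
$E = (10^{-1/m} - 1) \times 100\%$; values outside 90–110% are flagged
as a warning, not an error, since a mildly out-of-window assay still
yields interpretable relative quantities.

Back-calculation (`cq_to_copies()`) is the exact algebraic inverse of
the line. Extrapolation below the lowest standard is permitted and can
be flagged: field samples routinely sit below the standard range, and
refusing to back-calculate them would silently censor the data most
relevant to detection gating.

`ng_to_copies()` converts gravimetric standards (nanograms of plasmid)
to copies with the 660 g/mol/bp double-stranded average mass. The
construct length (vector + insert) must be supplied by the user; it is
a property of the cloning setup, not of the assay, and no sensible
default exists.

## Limit of detection

The LOD is defined as the concentration detected with 95% probability
(`lod_probability`, config-exposed). Rather than reading the first
dilution level with ≥95% observed detection — which is hostage to the
dilution grid — a detection-probability curve is fitted to the
per-concentration binomial counts and solved for the target.

Two candidate curves are fitted by maximum binomial likelihood and
compared by AIC:

* **Single-hit Poisson** (`poisson_cloglog`): $p(Q) = 1 - e^{-cQ}$,
  i.e. detection occurs iff the reaction contains at least one
  amplifiable template, with template counts Poisson-distributed around
  the nominal concentration. This is an intercept-only binomial GLM with
  a complementary-log-log link and offset $\log Q$. With $c = 1$ it
  yields the theoretical floor $-\ln(0.05) \approx 3$ copies/reaction.
* **Logistic in log10 Q** (`logistic_log10`): a flexible saturating
  alternative for assays whose detection falls off faster or slower than
  single-hit theory (e.g. aggregation, interfering matrix).

Two families suffice to cover saturating detection shapes; both are
monotone, which an LOD requires. A logistic fit with non-positive slope
is discarded. When the fitted probability already meets the target at
the lowest tested concentration, that concentration is reported with
`censored = TRUE` — the true LOD lies at or below the tested range and
the data cannot say where. A discrete (non-modelled) criterion is
available as `lod_method = "discrete"` for comparability with older
protocols.

## Limit of quantification

The LOQ bounds *quantification*, so its statistic is the CV of
back-calculated copy numbers among detected replicates — not the CV of
Cq, and not including non-detects, which have no copy estimate. Per
concentration, a CV needs at least two detected replicates.

Three candidate CV-vs-concentration curves are fitted by least squares
and compared by a common Gaussian AIC: exponential decay
$a e^{-bQ}$ in copies, linear in $\log_{10} Q$, and quadratic in
$\log_{10} Q$. Fitting the decay model against raw copies and the
polynomial family against log copies reflects their natural scales (a
decay in log space would be nearly linear and redundant). Exact fits tie
at zero residual sum of squares; the AIC computation floors the RSS so
ties resolve toward the smaller model, which makes model recovery on
noiseless data deterministic (linear data select linear, not the
quadratic that nests it).

The LOQ is the first concentration, scanning upward from the lowest
standard, at which the fitted CV drops to the threshold (35%,
config-exposed), refined by bisection on the bracketing interval. The
scan-then-bisect construction matters because the quadratic candidate
can be non-monotone; "first crossing from above" is then the only
defensible reading. If the fitted CV already meets the threshold at the
lowest standard the LOQ is censored there; if it never crosses within
the standards' range, the highest standard is reported censored, with a
warning.

`estimate_sensitivity()` enforces LOD ≤ LOQ by raising the reported LOQ
to the LOD with a diagnostic note when the independent fits disagree —
quantification can never be more sensitive than detection, and the rare
disagreements come from sampling noise at the lowest levels.

## Inhibition

The IPC inhibition statistic is the delay
$\Delta C_q = C_{q,\text{sample}} - C_{q,\text{control}}$. The sign
convention is chosen so that *inhibition is positive*: an inhibited
reaction crosses threshold later, and the correction
$2^{\Delta C_q} > 1$ inflates raw copies back toward their uninhibited
value (a 1.33-cycle delay corresponds to a 2.51-fold underestimate; a
3-cycle delay, the significance threshold, to ~10-fold). Negative
delays (apparent facilitation) are applied as-is by default, shrinking
copies symmetrically; `clip_negative_delta = TRUE` treats them as zero
delay for users who regard them as noise.

A non-amplified sample IPC leaves no finite correction. The delay is
reported as `Inf`, the sample is flagged as significant inhibition, and
its reactions are excluded from quantification with a warning —
inventing a finite correction factor there would fabricate
concentrations.

The control Cq is the mean over all clean IPC wells on the plate, and
the per-group delay averages each site–season's replicate IPC wells,
matching how field samples are normalized. IPC no-template wells must
not amplify; `check_ipc_controls()` rejects plates where they do, since
cross-reactive IPC primers invalidate the whole inhibition assay.

## Gating, units and aggregation

Normalization precedes gating: detection calls are made on
inhibition-corrected copies, so a heavily inhibited but genuinely
positive reaction is not misclassified as negative. The three-way gate
is: at or below LOD → `negative`; strictly between LOD and LOQ →
`detected_below_loq` (a detection, excluded from quantitative
summaries); at or above LOQ → `quantifiable`. Boundary conventions
follow "positive means greater than the LOD", so a value exactly at the
LOD is negative and a value exactly at the LOQ is quantifiable. A site
is scored positive when any replicate exceeds the LOD.

Copies per liter multiply copies/reaction by
$(V_\text{elution}/V_\text{template}) / V_\text{filtered}$ — ×50 with
the defaults (50 µL, 2 µL, 0.5 L) — and are analyzed as
$\log_{10}(x+1)$, which keeps true zeros at zero.

How negative replicates enter group means is genuinely underdetermined,
so both rules are implemented (`negative_fill`): the default
`zero_fill` counts them as zero copies/L, reading a detection failure as
evidence of at-most-trace concentration; `omit` averages quantifiable
replicates only, which estimates concentration *conditional on
quantifiability* and runs higher. Below-LOQ detections are excluded from
means under both rules but always count as detections. Fold changes are
computed on linear-scale mean concentrations, not on log-transformed
values — that is the scale on which published seasonal ratios reproduce
from their group means.

## Statistics

* **Pairwise Wilcoxon rank-sum**, two-sided, across species, seasons and
  stream classes: exact null distribution when both groups have ≤ 10
  observations without ties, normal approximation with tie and
  continuity correction otherwise. Being rank-based, results are
  identical on copies/L and on $\log_{10}(x+1)$ (asserted as a test).
  Families are Holm-adjusted by default — the conventional choice for
  pairwise rank tests; `bonferroni` and `none` are available since
  practice varies.
* **Welch's t-test** (unequal variances) for seasonal ΔCq: seasonal
  inhibition variances are visibly unequal in this kind of data, and
  Welch costs essentially nothing when they happen to be equal. Two
  constant equal groups return p = 1 by convention.
* **Spearman correlation** for ΔCq vs salinity: monotone association is
  the scientific claim, and salinity is bounded and skewed. Exact
  permutation p for n ≤ 8 without ties, t-approximation otherwise.

Significance stars use the conventional 0.05/0.01/0.001/0.0001
thresholds on adjusted p-values.

## The synthetic generator

No raw plate data accompany the study design this package targets, so
`simulate_dilution_series()` and `simulate_field_survey()` generate
plates with the statistical structure the analysis assumes:

* **Low-copy stochasticity** is purely Poisson: each well receives
  $k \sim \text{Poisson}(Q\,\varepsilon)$ amplifiable templates
  ($\varepsilon$ = per-molecule detection efficiency, default 1), is a
  non-detect iff $k = 0$, and otherwise reads
  $C_q = b + m \log_{10} k + \mathcal{N}(0, \sigma_{C_q})$. This single
  mechanism produces both the falling detection probability and the
  rising copy-CV at low concentrations that LOD/LOQ estimation relies
  on; no separate amplification-efficiency stochasticity is modelled.
* **Defaults**: slope −3.4149 cycles/decade and intercept 37.5 (a
  96.3%-efficiency assay), $\sigma_{C_q} = 0.2$ cycles, ten replicates
  at each of seven decades — a replication level typical of careful
  assay validation.
* **The default field design** (`yangyang_design()`) encodes a
  chum-salmon river survey: six sites (three mainstem, three tributary,
  numbered from downstream), two seasons, three replicate sub-samples
  per site, four species assays. Seasonal means for the dominant species
  are 1.09×10⁶ (spawning) and 1.71×10⁴ (non-spawning) copies/L; the
  minor species' spawning means derive from the published cross-species
  ratios (626-, 77- and 43-fold below the dominant species), and their
  non-spawning means — nowhere published — are set once at 1.0×10³ and
  1.5×10³ copies/L, the same order as the third species' published
  1.96×10³, consistent with three minor species that do not differ
  detectably in that season. Site-level inhibition delays span −0.33 to
  1.33 cycles with seasonal means 0.44 vs 0.07, and salinity declines
  upstream so that delay and salinity correlate positively.
* **Replicate variation** is lognormal with sd 0.3 on the log10 scale —
  roughly a factor-of-two spread replicate to replicate, a realistic
  dispersion for filtered sub-samples; no replicate dispersion is
  published for this design, so the value is a one-time choice.
* The volume factor (×50) is reused inversely when converting design
  means to per-reaction copies, so simulated and analyzed units
  round-trip exactly.

What the generator does **not** emulate: eDNA shedding, decay and
downstream transport; extraction efficiency and its variation; between-
assay calibration differences (all assays share one curve); plate
effects and pipetting error beyond Gaussian Cq noise; true inter-site
spatial correlation. Passing tests therefore demonstrate that the
*estimators recover what the generator injects* under the stated noise
model — they do not validate field accuracy, and assays moved to new
instruments, chemistries or sites still require re-validation.

One consequence worth noting: with 18 replicates per season and tight
lognormal dispersion, the simulated minor species can show seasonal
contrasts that field data of this design would not resolve; the
generator reproduces the *concentration structure*, not the power of
the original survey.

## Numerical choices and problem sizes

Model selection is by AIC everywhere, with RSS floored at 1e−12 in the
least-squares AIC so exact fits tie-break toward fewer parameters. The
LOQ threshold crossing uses a 512-point log-spaced scan plus 60
bisection steps (relative precision far below reporting precision).
GLM fitting failures or non-monotone fits simply eliminate a candidate;
if all candidates fail, the error says so rather than guessing.

Simulation-backed tests use sizes chosen to make their tolerances
meaningful at interactive runtimes: 1,000 replicates per concentration
for LOD recovery (±0.5 copies around the analytic value), 2,000–4,000
wells for detection-probability and CV checks, 2,000 null replicates
for the t-test size check, and single-survey or five-survey replicates
for end-to-end fold-change recovery with a declared two-sigma
Monte-Carlo band (a factor of 1.6 for one survey, since the log
fold-change has sd ≈ 0.25 under the default design).

## Limitations

The pipeline models detection and quantification at the reaction level;
it does not fit occupancy models, does not relate eDNA concentration to
biomass, and treats the LOD/LOQ as fixed assay properties rather than
per-plate random quantities. Inhibition correction assumes the IPC and
the target amplicon are inhibited equally, and the $2^{\Delta C_q}$
factor assumes perfect doubling — at 96% efficiency the correction is
conservative by about 2.5% per delayed cycle. All statistics treat
replicate reactions as exchangeable within groups.
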