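---
title: "Methods: epigenetic clocks, rate of aging, and the homocysteine threshold sweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic clocks, rate of aging, and the homocysteine threshold sweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiroa)
```

## The problem

Elevated plasma total homocysteine (tHcy) is a modifiable risk factor for
cognitive decline in older adults, and B-vitamin supplementation (B6,
folic acid, B12) lowers it. DNA-methylation "clocks" — linear predictors
over CpG beta values — estimate a biological ("epigenetic") age from a
blood sample. This package implements the analysis pipeline for asking,
in a two-arm placebo-controlled elderly cohort measured at baseline and
two years later: does high tHcy accelerate epigenetic aging, and does
lowering it with B-vitamins slow that acceleration?

The analysis unit is the **rate of aging**,

$$\mathrm{ROA} = \frac{\text{epigenetic age}}{\text{chronological age}},$$

with pace-of-aging clocks (which output a rate directly) passed through
unchanged, and the outcome of interest is its two-year change
$\Delta\mathrm{ROA} = \mathrm{ROA}_{t_2} - \mathrm{ROA}_{t_1}$ (positive =
acceleration).

## Clock architectures

`evaluate_clock()` supports the four architectures found across published
clocks:

* **identity** — epigenetic age is the affine score
  $a + \sum_j w_j \beta_{js}$;
* **horvath_age** — the score lives in a transformed age scale that is
  logarithmic below an adulthood constant $A$ (default 20) and linear
  above it; `horvath_age_inverse()` maps back to years via
  $(A+1)e^{x} - 1$ for $x<0$ and $x(A+1)+A$ otherwise (continuous and
  strictly increasing);
* **rate** — the score *is* the rate (DunedinPACE-style); ROA code never
  divides it by chronological age;
* **PC** — betas are centered probe-wise, projected onto component
  loadings, and component scores are combined linearly. This is the
  generic principal-component clock architecture; loadings and weights
  are user-supplied (proprietary coefficient sets are not shipped, nor
  are the published coefficient values of any named clock — the file
  format and transforms are the deliverable).

**Missing data.** A probe listed by a clock but absent from the array is
an error unless truncated evaluation is requested, in which case the
missing terms are dropped and the full intercept kept — mirroring how
truncated clocks are validated in practice (full vs truncated predictor
on a reference panel), rather than re-fitting the clock. An `NA` beta at
a present probe is imputed by the probe-wise reference mean with a logged
count, which keeps the predictor defined without shifting its scale.

**Truncation gate.** `truncation_overlap()` correlates the full and
truncated predictors across reference samples; a clock is included only
if $r \ge 0.9$, and the implied signal loss is $(1-r^2)\times 100\%$,
displayed with integer truncation (so $r = 0.901$ reads as an 18% loss).
Zero-variance predictors make the correlation undefined; the clock is
then excluded with a diagnostic rather than a numeric verdict.

## Statistics

* `pearson_regression()` / `pearson_pvalue()`: OLS plus the exact t
  transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df, two-sided.
* `group_ttest()`: the unpaired default is **Welch** with
  Welch–Satterthwaite df — the robust reading of an unqualified
  "unpaired two-tailed t test" — with a pooled-variance option for
  sensitivity checks; paired tests use the mean difference over its SE.
  Conventions for degenerate input: identical constant groups give
  $p = 1$; a zero-variance paired difference is an error.
* `hedges_g()`: Cohen's $d$ on the df-weighted pooled SD times
  $J = 1 - 3/(4N - 9)$; `classify_effect()` buckets $|g|$ at 0.2 / 0.5 /
  0.8 (lower edges inclusive — the published figures draw threshold lines
  only, so the boundary convention is ours and is fixed).
* `robust_regression()`: Huber M-estimation by IRLS, tuning constant
  1.345 on residuals standardized by the MAD (re-estimated each
  iteration), convergence at a coefficient change below 1e-8 or 50
  iterations (non-convergence returns the last iterate with a warning).
  When no standardized residual exceeds the constant, the result *is*
  OLS. "Robust regression" in the source analysis is otherwise
  unspecified; Huber is our choice and `MASS::rlm` serves as an
  independent oracle in the tests.
* `partial_correlation()`: "normalizing to baseline tHcy" is implemented
  as double residualization of both variables on tHcy. The method is
  unspecified in the source analysis; we chose the minimal covariate
  adjustment that is auditable — it equals the closed-form first-order
  partial correlation to $10^{-10}$, which the tests assert — and the
  p-value spends one extra df ($n-3$).

## The threshold sweep

Subjects are filtered to baseline tHcy $\ge$ threshold for thresholds 5.5
to 20.5 μmol/L in 0.5 steps (boundaries: minimum inclusive, maximum
exclusive, matching the clinical "≥15" / "<15" conventions). At each
threshold, per arm: the OLS slope of ΔROA on baseline tHcy with its SE
(arms with $n < 3$ are flagged, not dropped — the curve always spans the
grid, since the highest thresholds legitimately hold only a few
subjects); the bootstrapped between-group p-value; and Hedges' g.

**Bootstrap.** "Sampling 1000 times at n = 50" is read as 50 draws *per
group* with replacement, independently across arms — a between-group
t-test needs two samples, and 50 approximates per-arm subgroup sizes at
moderate thresholds. Each iteration's Welch p-value is recorded; the
summary is the mean and the 2.5/97.5 percentile interval (the p
distribution is bounded and skewed, so a normal approximation would be
wrong). Zero-variance-in-both-arms resamples count as $p = 1$ and are
logged. One master seed yields per-threshold child seeds by threshold
index (`child_seed()`), so extending the grid never reshuffles earlier
thresholds, and identical seeds reproduce the p-sample vector
bit-for-bit.

A caution established while testing: the "first significant threshold"
localizes the activation point of a hinge-shaped treatment effect only
at *moderate* effect-to-noise ratios. If the effect is strong relative to
noise, the affected upper-tail subjects make every lower threshold's
subgroup significant too, and the first significant threshold slides to
the bottom of the grid. The property and acceptance tests therefore
exercise localization at the default calibration, where it holds.

## The synthetic cohort

`generate_cohort()` states a world matching the published cohort's
summary statistics; these defaults are fixed and are not tuning knobs:

| parameter | default | why |
|---|---|---|
| subjects | 110/arm | published arm sizes (110/107) |
| age | truncated normal, mean 76.8, sd 4.9, min 70 | published means/SDs; 70+ inclusion rule |
| tHcy | lognormal, mean 12, sd 3.9 μmol/L | published means/SDs; positive right tail gives a realistic ≥15 subgroup (~19%) |
| baseline ROA | mean 0.84, sd 0.07 | published index-clock ROA moments |
| corr(tHcy, ROA) | 0.23 | published baseline correlation |
| ΔROA | hinge: slope·max(0, tHcy − 13) + noise | treatment effect confined to elevated tHcy, with a recoverable change point at τ = 13 |
| placebo hinge slope | calibrated | solved in closed form (lognormal partial moments) so the whole-arm linear corr(tHcy, ΔROA) is 0.24 |
| treated slope | −0.6 × placebo | reversal above the hinge |
| ΔROA noise sd | 0.03 | consistent with the published ROA SDs at the two timepoints (0.07/0.08) under high test–retest correlation |
| tHcy follow-up | ×0.7 under treatment | the ~30% lowering B-vitamins achieve |
| cognition | score = mean + sd(−κ·z(tHcy) + √(1−κ²)·ε), κ = 0.35 | scores load negatively on tHcy (timed tests positively), bounded to instrument ranges (MMSE ≤ 30) |

Methylation is generated per clock block: probe $j$ gets a baseline logit
$c_j$ and a signed sensitivity $d_j$ to the standardized latent target,
and $\beta_{js} = \mathrm{logistic}(c_j + d_j z_s + \varepsilon)$, which
is automatically in $[0,1]$. The clock's intercept and scale are then
solved by OLS of the latent target on the raw probe-weighted sum, so
evaluating the clock recovers the latent epigenetic age up to measurement
noise (r > 0.99 at the default logit noise of 0.08; the contract requires
> 0.95). Because the logistic link is only locally linear, the noiseless
case is near-exact rather than exact — the tests bound the residual
curvature (< 0.5 y) instead of asserting identity. One block per
architecture (identity, horvath_age, rate, PC) is generated so all four
evaluation paths run by default; the rate clock's latent pace is the
latent ROA shifted by +0.24 to the published pace scale (mean ≈ 1.08).

Latent truth (true ROA, ΔROA, epigenetic ages) is retained in the bundle
**only** for parameter-recovery tests; it is written to a separate
`latent_truth.csv` and never enters an analysis path.

**What a green test does not establish.** The generator emulates printed
moments and correlations, not array chemistry (probe types, dye bias),
batch effects, cell-composition shifts, or the true joint distribution of
tHcy and ΔROA (the underlying trial data are proprietary). Recovery of
the configured correlations shows the pipeline's statistics are wired
correctly — not that the biological findings replicate.

**A known fragile criterion.** In the ≥15 μmol/L subgroup (~20 subjects
per arm) the treated arm's population-level ΔROA~tHcy correlation under
the stated world is ≈ −0.21, and this value is invariant to the noise
scale (the calibrated slope rescales with it). The sampling SD of r at
that n is ≈ 0.23, so the *sign* of the treated subgroup slope is
recovered in only ~75% of seeds; at the package's default seed it comes
out (weakly) positive. The corresponding acceptance check is left
failing rather than re-seeded or weakened; see the test suite.

## Numerical choices

* Lognormal tHcy parameters are solved exactly from the target mean/SD;
  the hinge-slope calibration uses closed-form lognormal partial moments
  (no simulation in the generator's setup path).
* Ages are drawn by rejection from the truncated normal.
* p-values are reported at full precision; significance stars/bands are a
  formatting layer the package does not impose.
* Subjects missing methylation at either timepoint are excluded from
  ΔROA analyses with a logged count; cognitive scores are
  pairwise-deleted per test.
* All randomness flows from explicit seeds; stage and threshold streams
  are decoupled via `child_seed()` (an affine congruence on the 31-bit
  range), so outputs are reproducible byte-for-byte.

## Limitations

* The PC-clock path implements the generic linear PC architecture only;
  any nonlinear output calibration a commercial clock may apply is out of
  scope.
* Whether truncated clocks on a custom array should drop terms or impute
  probe means is not settled by the source analysis; term-dropping is our
  default and mean imputation applies only to sporadic `NA`s.
* No multiple-testing correction across clocks is applied (the per-clock
  tests are reported unadjusted, as in the source analysis).
* The workbench CLI orchestrates and validates; it computes no statistics
  of its own.
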