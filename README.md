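# epiroa

Epigenetic-clock **rate-of-aging** (ROA) analysis for two-arm intervention
cohorts, built around the question: *does elevated plasma homocysteine
(tHcy) accelerate epigenetic aging, and does lowering it with B-vitamins
slow that acceleration?*

The package is aimed at analysts working with DNA-methylation clock data
in intervention studies. It provides:

* **Clock evaluation** (`evaluate_clock`) from CpG beta-value matrices for
  four architectures: plain linear ("identity"), log-linear transformed
  age ("horvath_age", with the exact anti-transform), direct
  pace-of-aging ("rate"), and principal-component clocks (probe-wise
  centering → loadings → component weights). Coefficient tables are plain
  CSV; proprietary or published coefficient *values* are not shipped.
* **Truncation validation** (`truncation_overlap`): when an array lacks
  some of a clock's CpGs, the full and truncated predictors are
  correlated on a reference panel; clocks enter the analysis only if
  r ≥ 0.9, with signal loss (1 − r²)·100%.
* **ROA statistics** (`build_roa_table`, `pearson_regression`,
  `group_ttest`): ROA = epigenetic age / chronological age (rate clocks
  pass through), its two-year change ΔROA = ROA(t₂) − ROA(t₁), baseline
  correlation tables, and Welch/paired group tests.
* **The tHcy threshold sweep** (`run_threshold_sweep`): for thresholds
  5.5–20.5 μmol/L (step 0.5), per-arm OLS slopes of ΔROA on baseline
  tHcy, a seeded bootstrap of the between-group Welch p-value (1000
  resamples of 50 per group, mean and 95% percentile interval), and
  Hedges' g = J·d with J = 1 − 3/(4N − 9), classified at |g| ≥ 0.2 / 0.5 /
  0.8.
* **Cognition links** (`cognition_associations`): Pearson and Huber
  robust regression (IRLS, tuning 1.345, MAD scale) of ΔROA on baseline
  cognitive scores, with optional tHcy adjustment by double
  residualization (exact partial correlation).
* **A seeded synthetic cohort generator** (`generate_cohort`) emulating an
  elderly MCI trial population — lognormal tHcy (mean 12, sd 3.9 μmol/L),
  baseline corr(tHcy, ROA) = 0.23, a hinge-shaped treatment effect above
  τ = 13 μmol/L that reverses under treatment — so the full pipeline is
  testable with no external data.
* **A CLI workbench** (`epiroa_cli`) with `simulate | clocks | roa |
  sweep | cognition | report` subcommands and JSON run manifests.

## Worked example

```r
library(epiroa)

sim <- generate_cohort(sim_config(seed = 1))          # 110 subjects/arm
roa <- build_roa_table(sim$cohort, sim$beta_t1, sim$beta_t2, sim$clocks)

baseline_roa_correlations(roa, sim$cohort)[, c("clock", "r", "r_squared", "p_value")]
#>         clock     r r_squared  p_value
#> 1 sim_horvath 0.248    0.0616 0.000201
#> 2   sim_index 0.243    0.0590 0.000277
#> 3    sim_pace 0.237    0.0561 0.000394
#> 4      sim_pc 0.238    0.0565 0.000378
```

All four generated clocks recover the configured baseline tHcy–ROA
correlation of 0.23 (r ≈ 0.24, p < 0.001 at n = 220): higher homocysteine,
faster epigenetic aging.

```r
d <- roa[roa$clock == "sim_index", ]
idx <- match(d$subject_id, sim$cohort$subject_id)
deltas <- data.frame(arm = sim$cohort$arm[idx],
                     thcy_baseline = sim$cohort$thcy_baseline[idx],
                     delta_roa = d$delta_roa)
sweep <- run_threshold_sweep(deltas, sweep_config(seed = 1))
subset(sweep, threshold %in% c(11, 12, 13, 14, 15),
       select = c(threshold, n_placebo, n_treated, slope_placebo,
                  slope_treated, boot_p_mean, hedges_g_abs, effect_class))
#>    threshold n_placebo n_treated slope_placebo slope_treated boot_p_mean
#> 12        11        61        48        0.0054      -1.1e-03     2.4e-01
#> 14        12        53        37        0.0057      -4.5e-04     1.2e-01
#> 16        13        42        29        0.0049      -7.7e-04     1.6e-02
#> 18        14        31        22        0.0055      -4.5e-05     4.1e-03
#> 20        15        21        18        0.0051       9.5e-04     9.8e-05
#>    hedges_g_abs effect_class
#> 12         0.30        small
#> 14         0.41        small
#> 16         0.65       medium
#> 18         0.75       medium
#> 20         1.07        large

first_significant_threshold(sweep)
#> [1] 12.5
```

The placebo arm's ΔROA rises with baseline tHcy (slope ≈ +0.005 per
μmol/L) while the treated arm's does not; the mean bootstrapped p-value
drops below 0.05 at ≈ 12.5 μmol/L — recovering the configured activation
threshold τ = 13 — and the effect size grows from *small* to *large* as
the subgroup is restricted to higher tHcy.

```r
build_group_comparison(roa, sim$cohort, min_thcy = 13)[
  , c("clock", "n_placebo", "n_treated", "delta_placebo_mean",
      "delta_treated_mean", "p")]
#>         clock n_placebo n_treated delta_placebo_mean delta_treated_mean      p
#> 1 sim_horvath        42        29              0.019            -0.0044 0.0083
#> 2   sim_index        42        29              0.019            -0.0044 0.0051
#> 3    sim_pace        42        29              0.019            -0.0023 0.0102
#> 4      sim_pc        42        29              0.015            -0.0036 0.0271
```

Among subjects with baseline tHcy ≥ 13 μmol/L, the placebo arm
accelerates (mean ΔROA ≈ +0.019 over two years) while the treated arm
does not (≈ −0.004), a significant difference for every clock
architecture.

The same stages run from the command line:

```sh
Rscript -e 'epiroa::epiroa_cli()' simulate --seed 1 --out runs/sim
Rscript -e 'epiroa::epiroa_cli()' sweep \
  --sample-sheet runs/sim/sample_sheet.csv \
  --beta-t1 runs/sim/beta_t1.csv --beta-t2 runs/sim/beta_t2.csv \
  --clocks runs/sim/clocks.csv --clock sim_index --seed 1 --out runs/sweep
```

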