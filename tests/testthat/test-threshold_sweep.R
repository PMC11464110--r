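test_that("sweep_config validates its fields", {
  expect_error(sweep_config(thresholds = c(5, 5)), "increasing")
  expect_error(sweep_config(m = 1), "m must be")
  cfg <- sweep_config()
  expect_equal(cfg$thresholds, seq(5.5, 20.5, by = 0.5))
  expect_equal(cfg$n_boot, 1000L)
  expect_equal(cfg$m, 50L)
})

test_that("sweep_slopes recovers exact linear constructions and flags degenerate points", {
  # noiseless hinge-free construction: slopes recovered exactly everywhere
  # both arms have n >= 3
  set.seed(21)
  thcy <- runif(120, 6, 21)
  d <- data.frame(arm = rep(c("placebo", "bvitamin"), 60),
                  thcy_baseline = thcy,
                  delta_roa = NA_real_)
  d$delta_roa[d$arm == "placebo"] <- 0.01 * (d$thcy_baseline[d$arm == "placebo"] - 10)
  d$delta_roa[d$arm == "bvitamin"] <- -0.005 * (d$thcy_baseline[d$arm == "bvitamin"] - 10)
  sl <- sweep_slopes(d, sweep_config(seed = 1))
  ok <- sl$n_placebo >= 3 & sl$n_treated >= 3
  expect_equal(sl$slope_placebo[ok], rep(0.01, sum(ok)))
  expect_equal(sl$slope_treated[ok], rep(-0.005, sum(ok)))

  # identically zero response -> all slopes 0
  z <- d; z$delta_roa <- 0
  slz <- sweep_slopes(z, sweep_config(seed = 1))
  ok <- slz$n_placebo >= 3 & slz$n_treated >= 3
  expect_equal(slz$slope_placebo[ok], rep(0, sum(ok)))
  expect_equal(slz$slope_treated[ok], rep(0, sum(ok)))

  # a threshold retaining < 3 subjects in an arm is flagged undefined
  tiny <- data.frame(arm = c(rep("placebo", 2), rep("bvitamin", 5)),
                     thcy_baseline = c(16, 17, 15, 16, 17, 18, 19),
                     delta_roa = rnorm(7))
  slt <- sweep_slopes(tiny, sweep_config(thresholds = 15, seed = 1))
  expect_true(is.na(slt$slope_placebo))
  expect_true(slt$degenerate)
  expect_equal(slt$n_placebo, 2L)
})

test_that("sweep slopes at the lowest threshold equal the whole-group regression", {
  d <- hinge_deltas(n_per_arm = 80, noise = 0.02, seed = 5)
  cfg <- sweep_config(thresholds = c(min(d$thcy_baseline) - 1, 10), seed = 2)
  sl <- sweep_slopes(d, cfg)
  for (arm in c("placebo", "bvitamin")) {
    whole <- pearson_regression(d$thcy_baseline[d$arm == arm],
                                d$delta_roa[d$arm == arm])
    col <- if (arm == "placebo") "slope_placebo" else "slope_treated"
    expect_equal(sl[[col]][1], whole$slope)
  }
})

test_that("bootstrap_group_p is deterministic, calibrated under the null, and powered", {
  set.seed(77)
  a <- rnorm(200); b <- rnorm(200)

  r1 <- bootstrap_group_p(a, b, n_boot = 400, m = 50, seed = 99)
  r2 <- bootstrap_group_p(a, b, n_boot = 400, m = 50, seed = 99)
  expect_identical(r1$p_samples, r2$p_samples)
  expect_length(r1$p_samples, 400L)
  expect_true(all(r1$p_samples >= 0 & r1$p_samples <= 1))
  expect_lte(r1$boot_p_ci[1], r1$boot_p_mean)
  expect_gte(r1$boot_p_ci[2], r1$boot_p_mean)

  # same-distribution groups: boot_p_mean centers on 0.5 in expectation
  # over data draws (a single dataset's bootstrap p distribution centers
  # on that dataset's own chance difference, so we average over draws)
  set.seed(101)
  means <- replicate(30, {
    bootstrap_group_p(rnorm(200), rnorm(200), n_boot = 100, m = 50,
                      seed = sample.int(1e6, 1))$boot_p_mean
  })
  expect_lt(abs(mean(means) - 0.5), 0.05)

  # gross separation forces near-zero p
  sep <- bootstrap_group_p(a, a + 10 * sd(a), n_boot = 400, m = 50, seed = 99)
  expect_lt(sep$boot_p_mean, 0.001)

  # per-iteration p agrees with t.test on a reconstructed resample
  set.seed(31); aa <- rnorm(40); bb <- rnorm(40, 1)
  one <- bootstrap_group_p(aa, bb, n_boot = 3, m = 10, seed = 5)
  set.seed(5L)
  A <- matrix(aa[sample.int(40, 30, replace = TRUE)], 10)
  B <- matrix(bb[sample.int(40, 30, replace = TRUE)], 10)
  expect_equal(one$p_samples[2], t.test(A[, 2], B[, 2])$p.value)

  # zero-variance resamples contribute p = 1
  expect_message(
    degen <- bootstrap_group_p(rep(1, 3), rep(1, 3), n_boot = 10, m = 5, seed = 1),
    "zero variance")
  expect_equal(degen$boot_p_mean, 1)
})

test_that("hedges_g matches the hand computation and its conventions", {
  # a = (1,2,3), b = (2,3,4): pooled SD 1, d = -1, J = 1 - 3/15 = 0.8
  eff <- hedges_g(c(1, 2, 3), c(2, 3, 4))
  expect_equal(eff$d, -1)
  expect_equal(eff$j, 0.8)
  expect_equal(eff$g, -0.8)
  expect_equal(eff$magnitude, 0.8)

  # equal means -> g = 0; swapping groups negates g
  expect_equal(hedges_g(c(1, 3), c(2, 2))$g, 0)
  set.seed(2); x <- rnorm(15); y <- rnorm(20, 1)
  expect_equal(hedges_g(x, y)$g, -hedges_g(y, x)$g)
  expect_true(eff$j > 0 && eff$j < 1)
  expect_error(hedges_g(rep(1, 3), rep(1, 4)), "pooled SD")

  # J -> 1 as n grows: g approaches Cohen's d
  set.seed(4)
  big <- hedges_g(rnorm(1e4), rnorm(1e4, 0.3))
  expect_equal(big$g, big$d, tolerance = 1e-3)
  expect_gt(big$j, 0.9999)
})

test_that("classify_effect uses absolute value with inclusive lower edges", {
  expect_equal(classify_effect(0), "none")
  expect_equal(classify_effect(0.2), "small")
  expect_equal(classify_effect(0.5), "medium")
  expect_equal(classify_effect(-0.8), "large")
  expect_equal(classify_effect(c(0.19, 0.49, 0.79, 2)),
               c("none", "small", "medium", "large"))
})

test_that("run_threshold_sweep localizes a hinge treatment effect", {
  # at the default calibration (hinge slope sized for a whole-arm r of
  # 0.24, reversal -0.6, noise 0.03) the dilution of the hinge effect at
  # low thresholds keeps the arms indistinct there, and the first
  # significant threshold lands in a neighborhood of tau = 13; the arm
  # slope separation at tau exceeds 3x the slope SE at this n
  slope <- sim_config()$placebo_delta_slope
  d <- hinge_deltas(n_per_arm = 150, tau = 13, slope = slope,
                    reversal = -0.6, noise = 0.03, seed = 33)
  sw <- run_threshold_sweep(d, sweep_config(n_boot = 300, seed = 3))
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 31L)
  at13 <- sw[sw$threshold == 13, ]
  expect_gt(at13$slope_placebo - at13$slope_treated,
            3 * max(at13$se_placebo, at13$se_treated))
  first <- first_significant_threshold(sw)
  expect_gte(first, 11.5)
  expect_lte(first, 14.5)
  # well below the hinge the arms are close to indistinct
  expect_gt(min(sw$boot_p_mean[sw$threshold <= 8], na.rm = TRUE), 0.05)

  # reproducibility of the whole sweep under one master seed
  sw2 <- run_threshold_sweep(d, sweep_config(n_boot = 300, seed = 3))
  expect_identical(sw$boot_p_mean, sw2$boot_p_mean)

  # child-seed derivation: earlier thresholds unchanged when the grid grows
  short <- run_threshold_sweep(d, sweep_config(thresholds = seq(5.5, 10, 0.5),
                                               n_boot = 300, seed = 3))
  expect_identical(short$boot_p_mean,
                   sw$boot_p_mean[seq_len(nrow(short))])
})
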