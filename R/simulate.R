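#' Configuration for the synthetic cohort generator
#'
#' Defaults state the world the generator emulates: an elderly (70+)
#' mild-cognitive-impairment trial population randomized 1:1 to placebo or
#' B-vitamins, with plasma tHcy around 12 micromol/L with a right tail
#' above 15, a positive baseline tHcy-ROA correlation of 0.23, a placebo
#' correlation of about 0.24 between baseline tHcy and the two-year ROA
#' change entering through a hinge above `tau` = 13 micromol/L, a treated
#' arm whose slope is reversed (multiplier -0.6) above the same hinge, and
#' cognitive scores loaded negatively on tHcy.
#'
#' @param n_per_arm subjects per arm, default 110.
#' @param age_mean,age_sd,age_min truncated-normal chronological age
#'   parameters (years), defaults 76.8 / 4.9 / 70.
#' @param thcy_mean,thcy_sd target moments of the lognormal baseline tHcy
#'   (micromol/L), defaults 12 / 3.9.
#' @param roa_mean,roa_sd latent baseline ROA moments, defaults 0.84 / 0.07.
#' @param rho_baseline target correlation of baseline tHcy with baseline
#'   ROA, default 0.23.
#' @param rho_delta_placebo target placebo-arm correlation of baseline tHcy
#'   with the two-year ROA change; the hinge slope is calibrated from the
#'   lognormal moments to hit it, default 0.24.
#' @param placebo_delta_slope hinge slope (change in delta-ROA per
#'   micromol/L above `tau`) for the placebo arm; `NULL` (default)
#'   calibrates it from `rho_delta_placebo`.
#' @param tau effect-activation threshold in micromol/L, default 13.
#' @param treatment_reversal multiplier applied to the placebo hinge slope
#'   in the treated arm, default -0.6 (a reversal).
#' @param delta_noise_sd SD of the ROA-change noise, default 0.03.
#' @param thcy_lowering multiplicative follow-up tHcy reduction in the
#'   treated arm, default 0.7 (a 30 percent lowering).
#' @param n_probes_per_clock CpG probes per generated clock, default 50.
#' @param beta_noise_sd logit-scale measurement noise per probe, default
#'   0.08 (calibrated so recovered epigenetic age correlates > 0.95 with
#'   the latent value).
#' @param n_components principal components for the generated PC clock,
#'   default 10.
#' @param cognition_loading strength of the tHcy-cognition link (fraction
#'   of score SD carried by standardized tHcy), default 0.35.
#' @param seed master seed; all stages derive child seeds from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 110L,
                       age_mean = 76.8, age_sd = 4.9, age_min = 70,
                       thcy_mean = 12, thcy_sd = 3.9,
                       roa_mean = 0.84, roa_sd = 0.07,
                       rho_baseline = 0.23,
                       rho_delta_placebo = 0.24,
                       placebo_delta_slope = NULL,
                       tau = 13, treatment_reversal = -0.6,
                       delta_noise_sd = 0.03,
                       thcy_lowering = 0.7,
                       n_probes_per_clock = 50L,
                       beta_noise_sd = 0.08,
                       n_components = 10L,
                       cognition_loading = 0.35,
                       seed = 1L) {
  stopifnot(n_per_arm >= 4L, age_sd > 0, thcy_sd > 0, roa_sd > 0,
            age_min < age_mean, delta_noise_sd > 0, n_probes_per_clock >= 2L)
  if (abs(rho_baseline) >= 1) stop("rho_baseline must lie in (-1, 1)", call. = FALSE)
  cfg <- list(n_per_arm = as.integer(n_per_arm), age_mean = age_mean,
              age_sd = age_sd, age_min = age_min, thcy_mean = thcy_mean,
              thcy_sd = thcy_sd, roa_mean = roa_mean, roa_sd = roa_sd,
              rho_baseline = rho_baseline,
              rho_delta_placebo = rho_delta_placebo,
              placebo_delta_slope = placebo_delta_slope,
              tau = tau, treatment_reversal = treatment_reversal,
              delta_noise_sd = delta_noise_sd, thcy_lowering = thcy_lowering,
              n_probes_per_clock = as.integer(n_probes_per_clock),
              beta_noise_sd = beta_noise_sd,
              n_components = as.integer(n_components),
              cognition_loading = cognition_loading, seed = as.integer(seed))
  if (is.null(cfg$placebo_delta_slope)) {
    cfg$placebo_delta_slope <- calibrate_delta_slope(cfg)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Lognormal parameters hitting the configured tHcy mean and SD.
thcy_lognormal_params <- function(cfg) {
  s2 <- log(1 + (cfg$thcy_sd / cfg$thcy_mean)^2)
  list(meanlog = log(cfg$thcy_mean) - s2 / 2, sdlog = sqrt(s2))
}

# Closed-form lognormal partial moments give cov(X, h) and var(h) for the
# hinge h = max(0, X - tau); the placebo hinge slope is then solved so the
# *linear* correlation of X with slope * h + noise equals the target.
calibrate_delta_slope <- function(cfg) {
  lp <- thcy_lognormal_params(cfg)
  mu <- lp$meanlog; s <- lp$sdlog; tau <- cfg$tau
  zp <- function(k) stats::pnorm((mu + k * s^2 - log(tau)) / s)
  P  <- zp(0)                                   # P(X > tau)
  m1 <- exp(mu + s^2 / 2) * zp(1)               # E[X 1{X>tau}]
  m2 <- exp(2 * mu + 2 * s^2) * zp(2)           # E[X^2 1{X>tau}]
  Eh  <- m1 - tau * P
  Eh2 <- m2 - 2 * tau * m1 + tau^2 * P
  Exh <- m2 - tau * m1
  Ex  <- exp(mu + s^2 / 2)
  cov_xh <- Exh - Ex * Eh
  var_h <- Eh2 - Eh^2
  sd_x <- sqrt((exp(s^2) - 1) * exp(2 * mu + s^2))
  r <- cfg$rho_delta_placebo
  k <- cov_xh / sd_x
  disc <- k^2 - r^2 * var_h
  if (disc <= 0) stop("infeasible calibration: requested correlation too high for the hinge", call. = FALSE)
  r * cfg$delta_noise_sd / sqrt(disc)
}

rtruncnorm_min <- function(n, mean, sd, lo) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo])
  }
  out[seq_len(n)]
}

# Instrument panel: mean, sd, lower/upper bounds, and direction of the
# tHcy loading (+1 = higher tHcy lowers the score; -1 for timed tests
# where worse performance is a *higher* number).
cognitive_panel <- function() {
  data.frame(
    test = c("hvlt_r_dr", "hvlt_r_tr", "mmse", "category_fluency",
             "graded_naming", "srm", "trail_a", "trail_b", "sdmt",
             "map_search"),
    mean = c(7.5, 26, 28.2, 20, 20, 16, 50, 120, 35, 60),
    sd = c(3.1, 5, 1.5, 5, 5, 2.5, 20, 50, 10, 15),
    lo = c(0, 0, 0, 0, 0, 0, 5, 10, 0, 0),
    hi = c(12, 36, 30, Inf, 30, 20, Inf, Inf, Inf, Inf),
    dir = c(1, 1, 1, 1, 1, 1, -1, -1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic two-arm cohort with methylation and clocks
#'
#' Draws a seeded cohort with the structure described in [sim_config()]:
#' truncated-normal ages, lognormal baseline tHcy, 1:1 randomization,
#' latent baseline ROA correlated with tHcy, a two-year ROA change driven
#' by a hinge in tHcy above `tau` whose slope reverses under treatment,
#' cognitive scores loaded on tHcy, and — for each of the four clock
#' architectures (identity, horvath_age, rate, PC) — a probe block in the
#' beta matrices plus a matching calibrated clock definition. Latent truth
#' is retained only for parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_cohort`: `cohort` (sample sheet
#'   data.frame), `beta_t1`, `beta_t2` ([beta_matrix()]), `clocks` (named
#'   list of [clock_definition()]), `latent` (data.frame with the true
#'   per-subject `roa_t1`, `delta_roa`, epigenetic ages), and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- 2L * cfg$n_per_arm
  subject_id <- sprintf("S%04d", seq_len(n))

  age1 <- rtruncnorm_min(n, cfg$age_mean, cfg$age_sd, cfg$age_min)
  age2 <- age1 + 2
  lp <- thcy_lognormal_params(cfg)
  thcy <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
  arm <- sample(rep(c("placebo", "bvitamin"), each = cfg$n_per_arm))

  # latent baseline ROA, linear in tHcy at the target correlation
  lambda <- cfg$rho_baseline * cfg$roa_sd / cfg$thcy_sd
  roa1 <- cfg$roa_mean + lambda * (thcy - cfg$thcy_mean) +
    stats::rnorm(n, 0, cfg$roa_sd * sqrt(1 - cfg$rho_baseline^2))

  # two-year change: hinge above tau, reversed slope under treatment
  hinge <- pmax(0, thcy - cfg$tau)
  slope <- ifelse(arm == "placebo", cfg$placebo_delta_slope,
                  cfg$treatment_reversal * cfg$placebo_delta_slope)
  droa <- slope * hinge + stats::rnorm(n, 0, cfg$delta_noise_sd)
  roa2 <- roa1 + droa

  epi1 <- roa1 * age1
  epi2 <- roa2 * age2
  pace_offset <- 0.24 # shifts latent ROA (mean 0.84) to a pace scale (mean 1.08)

  thcy2 <- thcy * ifelse(arm == "bvitamin", cfg$thcy_lowering, 1) *
    exp(stats::rnorm(n, 0, 0.05))

  panel <- cognitive_panel()
  kappa <- cfg$cognition_loading
  zt <- (thcy - mean(thcy)) / stats::sd(thcy)
  cog <- sapply(seq_len(nrow(panel)), function(j) {
    p <- panel[j, ]
    raw <- p$mean + p$sd * (-kappa * p$dir * zt +
                              sqrt(1 - kappa^2) * stats::rnorm(n))
    pmin(pmax(raw, p$lo), p$hi)
  })
  colnames(cog) <- panel$test

  cohort <- data.frame(subject_id = subject_id, arm = arm,
                       age_baseline = age1, age_followup = age2,
                       thcy_baseline = thcy, thcy_followup = thcy2,
                       cog, stringsAsFactors = FALSE)

  blocks <- list(
    sim_index   = list(target1 = epi1, target2 = epi2, transform = "identity"),
    sim_horvath = list(target1 = epi1, target2 = epi2, transform = "horvath_age"),
    sim_pace    = list(target1 = roa1 + pace_offset, target2 = roa2 + pace_offset,
                       transform = "rate"),
    sim_pc      = list(target1 = epi1, target2 = epi2, transform = "pc")
  )
  clocks <- list()
  b1 <- list(); b2 <- list()
  for (i in seq_along(blocks)) {
    bl <- blocks[[i]]
    gen <- generate_beta_and_clocks(
      bl$target1, bl$target2, cfg, name = names(blocks)[i],
      transform = bl$transform,
      probe_prefix = sprintf("cg%02d", i),
      seed = child_seed(cfg$seed, i))
    colnames(gen$beta_t1) <- subject_id
    colnames(gen$beta_t2) <- subject_id
    clocks[[names(blocks)[i]]] <- gen$clock
    b1[[i]] <- gen$beta_t1; b2[[i]] <- gen$beta_t2
  }

  structure(list(
    cohort = cohort,
    beta_t1 = beta_matrix(do.call(rbind, b1)),
    beta_t2 = beta_matrix(do.call(rbind, b2)),
    clocks = clocks,
    latent = data.frame(subject_id = subject_id, roa_t1 = roa1,
                        roa_t2 = roa2, delta_roa = droa,
                        epigenetic_age_t1 = epi1, epigenetic_age_t2 = epi2,
                        stringsAsFactors = FALSE),
    config = cfg), class = "synthetic_cohort")
}

#' Generate a probe block and a calibrated clock for a latent target
#'
#' Each probe gets a baseline logit and a signed sensitivity to the
#' standardized latent target; beta values are
#' `logistic(c_j + d_j * z_s + noise)` (automatically inside `[0, 1]`).
#' The clock's intercept and scale are then solved by OLS of the latent
#' target on the raw probe-weighted sum at baseline so that
#' [evaluate_clock()] recovers the latent values up to measurement noise
#' (correlation > 0.95 at the default noise). For `transform = "pc"` the
#' loadings come from a principal-component decomposition of the baseline
#' block and the component weights are fit to the target.
#'
#' @param target_t1,target_t2 latent per-sample values (epigenetic ages in
#'   years, transformed ages, or rates) at the two timepoints.
#' @param config a [sim_config()] (probe count and noise are read from it).
#' @param name clock name.
#' @param transform `"identity"`, `"horvath_age"`, `"rate"` or `"pc"`
#'   (`"pc"` produces an identity-transform clock with a PC block).
#' @param probe_prefix prefix for generated probe ids.
#' @param seed stream seed for this block.
#' @return A list: `clock` ([clock_definition()]), `beta_t1`, `beta_t2`
#'   (plain matrices, probes x samples).
#' @export
generate_beta_and_clocks <- function(target_t1, target_t2, config,
                                     name = "sim_clock",
                                     transform = "identity",
                                     probe_prefix = "cg",
                                     seed = 1L) {
  cfg <- config
  set.seed(as.integer(seed))
  J <- cfg$n_probes_per_clock
  n <- length(target_t1)
  probes <- sprintf("%s%06d", probe_prefix, seq_len(J))

  # the clock is fit in "raw" space: transformed age for horvath clocks
  raw1 <- if (transform == "horvath_age") horvath_age_forward(target_t1) else target_t1
  raw2 <- if (transform == "horvath_age") horvath_age_forward(target_t2) else target_t2
  m0 <- mean(raw1); s0 <- stats::sd(raw1)
  z1 <- (raw1 - m0) / s0
  z2 <- (raw2 - m0) / s0

  cj <- stats::rnorm(J, 0, 0.8)
  dj <- sample(c(-1, 1), J, replace = TRUE) * stats::runif(J, 0.10, 0.25)
  mk <- function(z) {
    arg <- outer(cj, rep(1, n)) + outer(dj, z) +
      matrix(stats::rnorm(J * n, 0, cfg$beta_noise_sd), J, n)
    b <- stats::plogis(arg)
    rownames(b) <- probes
    b
  }
  beta1 <- mk(z1)
  beta2 <- mk(z2)

  # weights aligned with each probe's direction; intercept/scale solved by
  # OLS so the evaluated clock recovers the latent target at baseline
  w <- sign(dj) * stats::runif(J, 0.5, 1.5)
  names(w) <- probes

  if (transform == "pc") {
    K <- min(cfg$n_components, J, n - 1L)
    pca <- stats::prcomp(t(beta1), center = TRUE, scale. = FALSE)
    L <- pca$rotation[, seq_len(K), drop = FALSE]
    centers <- pca$center
    scores <- t(L) %*% (beta1 - centers)
    fit <- stats::lm(raw1 ~ t(scores))
    cw <- stats::setNames(stats::coef(fit)[-1L], colnames(L))
    cw[is.na(cw)] <- 0
    clock <- clock_definition(name, weights = cw,
                              intercept = unname(stats::coef(fit)[1L]),
                              transform = "identity",
                              pc_block = list(loadings = L, centers = centers,
                                              component_weights = cw))
  } else {
    s <- drop(crossprod(beta1, w))
    fit <- stats::lm(raw1 ~ s)
    clock <- clock_definition(name, weights = unname(stats::coef(fit)[2L]) * w,
                              intercept = unname(stats::coef(fit)[1L]),
                              transform = transform)
  }
  list(clock = clock, beta_t1 = beta1, beta_t2 = beta2)
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits the same delimited formats the analysis stages consume: the sample
#' sheet, both beta matrices, the clock coefficient table (with PC
#' companions), and the latent-truth table (test use only).
#'
#' @param sim a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    beta_t1 = file.path(dir, "beta_t1.csv"),
    beta_t2 = file.path(dir, "beta_t2.csv"),
    clocks = file.path(dir, "clocks.csv"),
    latent = file.path(dir, "latent_truth.csv"))
  utils::write.csv(sim$cohort, paths["sample_sheet"], row.names = FALSE)
  write_beta_matrix(sim$beta_t1, paths["beta_t1"])
  write_beta_matrix(sim$beta_t2, paths["beta_t2"])
  write_clock_definitions(sim$clocks, paths["clocks"])
  utils::write.csv(sim$latent, paths["latent"], row.names = FALSE)
  invisible(paths)
}
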