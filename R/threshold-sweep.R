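#' Configuration for the homocysteine threshold sweep
#'
#' @param thresholds strictly increasing minimum-inclusion tHcy levels in
#'   micromol/L; default 5.5 to 20.5 in 0.5 steps.
#' @param n_boot bootstrap resample count per threshold, default 1000.
#' @param m per-group resample size, default 50.
#' @param seed master seed; per-threshold child seeds are derived
#'   deterministically via [child_seed()] so adding thresholds never
#'   shuffles earlier results.
#' @param alpha significance level used by consumers, default 0.05.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(thresholds = seq(5.5, 20.5, by = 0.5),
                         n_boot = 1000, m = 50, seed = 1L, alpha = 0.05) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  structure(list(thresholds = thresholds, n_boot = as.integer(n_boot),
                 m = as.integer(m), seed = as.integer(seed), alpha = alpha),
            class = "sweep_config")
}

#' Per-arm regression slopes across tHcy thresholds
#'
#' At each threshold, subjects with baseline tHcy at or above it are
#' retained per arm, and the OLS slope of the two-year ROA change on
#' baseline tHcy is recorded with its standard error. Thresholds where an
#' arm has fewer than 3 subjects are emitted with `NA` slopes and
#' `degenerate = TRUE` rather than dropped, so the curve always covers the
#' configured range.
#'
#' @param deltas data.frame with columns `arm` (`placebo` / `bvitamin`),
#'   `thcy_baseline`, `delta_roa`.
#' @param config a [sweep_config()].
#' @return A data.frame with one row per threshold: counts, slopes, slope
#'   SEs, residual SEs, and a `degenerate` flag.
#' @export
sweep_slopes <- function(deltas, config = sweep_config()) {
  stopifnot(all(c("arm", "thcy_baseline", "delta_roa") %in% names(deltas)))
  one_arm <- function(d) {
    n <- nrow(d)
    # OLS by hand: unlike pearson_regression this stays defined for a
    # constant response (slope 0), which the null-response case produces
    if (n < 3L || stats::sd(d$thcy_baseline) == 0) {
      return(data.frame(n = n, slope = NA_real_, slope_se = NA_real_,
                        residual_se = NA_real_))
    }
    x <- d$thcy_baseline; y <- d$delta_roa
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    rss <- sum((y - mean(y) - slope * (x - mean(x)))^2)
    s2 <- rss / (n - 2)
    data.frame(n = n, slope = slope, slope_se = sqrt(s2 / sxx),
               residual_se = sqrt(s2))
  }
  rows <- lapply(config$thresholds, function(th) {
    sub <- deltas[deltas$thcy_baseline >= th, , drop = FALSE]
    p <- one_arm(sub[sub$arm == "placebo", , drop = FALSE])
    b <- one_arm(sub[sub$arm == "bvitamin", , drop = FALSE])
    data.frame(threshold = th,
               n_placebo = p$n, n_treated = b$n,
               slope_placebo = p$slope, se_placebo = p$slope_se,
               resid_se_placebo = p$residual_se,
               slope_treated = b$slope, se_treated = b$slope_se,
               resid_se_treated = b$residual_se,
               degenerate = is.na(p$slope) || is.na(b$slope))
  })
  do.call(rbind, rows)
}

# Vectorized Welch p-values over columns of two resample matrices (m x B).
# Iterations where both columns have zero variance get p = 1 by convention.
welch_p_columns <- function(A, B) {
  m <- nrow(A)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSums((A - rep(ma, each = m))^2) / (m - 1)
  vb <- colSums((B - rep(mb, each = m))^2) / (m - 1)
  se2 <- va / m + vb / m
  p <- rep(1, ncol(A))
  ok <- se2 > 0
  tstat <- (ma[ok] - mb[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((va[ok] / m)^2 / (m - 1) + (vb[ok] / m)^2 / (m - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  p
}

#' Bootstrapped between-group p-value
#'
#' Draws `m` observations with replacement from each group independently,
#' computes a Welch two-tailed t-test p-value between the resamples, and
#' repeats `n_boot` times. Returns the mean bootstrapped p-value and the
#' 2.5/97.5 percentile interval of the p distribution. Resamples with zero
#' variance in both arms contribute `p = 1` and their count is reported.
#' Identical seeds reproduce identical `p_samples` bit for bit.
#'
#' @param a,b numeric vectors (one per group), non-empty.
#' @param n_boot number of bootstrap iterations, default 1000.
#' @param m per-group resample size, default 50.
#' @param seed integer seed for the resampling stream.
#' @return A list: `boot_p_mean`, `boot_p_ci` (length 2), `p_samples`
#'   (length `n_boot`), `n_degenerate`.
#' @export
bootstrap_group_p <- function(a, b, n_boot = 1000, m = 50, seed = 1L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty", call. = FALSE)
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  A <- matrix(a[sample.int(length(a), n_boot * m, replace = TRUE)], nrow = m)
  B <- matrix(b[sample.int(length(b), n_boot * m, replace = TRUE)], nrow = m)
  p <- welch_p_columns(A, B)
  n_degen <- sum(apply_zero_var(A) & apply_zero_var(B))
  if (n_degen > 0) message(sprintf("epiroa: %d bootstrap iteration(s) with zero variance in both arms (p = 1)", n_degen))
  list(boot_p_mean = mean(p),
       boot_p_ci = unname(stats::quantile(p, c(0.025, 0.975), type = 7)),
       p_samples = p,
       n_degenerate = n_degen)
}

apply_zero_var <- function(M) {
  apply(M, 2L, function(col) all(col == col[1L]))
}

#' Hedges' g standardized effect size
#'
#' Cohen's d on the pooled (df-weighted) standard deviation, multiplied by
#' the small-sample correction `J = 1 - 3 / (4 * (n_a + n_b) - 9)`. The
#' sign follows `mean(a) - mean(b)`.
#'
#' @param a,b numeric vectors, each with at least 2 observations and a
#'   positive pooled SD.
#' @return A list: `g`, `d` (uncorrected), `j` (correction factor),
#'   `magnitude` (`|g|`).
#' @export
hedges_g <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need n >= 2 per group", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled SD; effect size undefined", call. = FALSE)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  j <- 1 - 3 / (4 * (na + nb) - 9)
  list(g = j * d, d = d, j = j, magnitude = abs(j * d))
}

#' Classify an effect size on the Sawilowsky-style scale
#'
#' Absolute-value thresholds, inclusive at the lower edge:
#' `|g| >= 0.8` large, `>= 0.5` medium, `>= 0.2` small, else none.
#'
#' @param g Hedges' g (signed; the absolute value is classified).
#' @return One of `"none"`, `"small"`, `"medium"`, `"large"` (vectorized).
#' @export
classify_effect <- function(g) {
  m <- abs(g)
  out <- ifelse(m >= 0.8, "large",
                ifelse(m >= 0.5, "medium",
                       ifelse(m >= 0.2, "small", "none")))
  out[!is.finite(m)] <- NA_character_
  out
}

#' Run the full homocysteine threshold sweep
#'
#' Combines, per threshold: per-arm regression slopes of the two-year ROA
#' change on baseline tHcy ([sweep_slopes()]), the bootstrapped
#' between-group p-value ([bootstrap_group_p()]), and Hedges' g with its
#' classification. Thresholds where an arm has fewer than 2 subjects get
#' `NA` bootstrap and effect-size fields.
#'
#' @param deltas data.frame with `arm`, `thcy_baseline`, `delta_roa`.
#' @param config a [sweep_config()].
#' @return A data.frame of class `sweep_result`, one row per threshold.
#' @export
run_threshold_sweep <- function(deltas, config = sweep_config()) {
  slopes <- sweep_slopes(deltas, config)
  extra <- lapply(seq_along(config$thresholds), function(i) {
    th <- config$thresholds[i]
    sub <- deltas[deltas$thcy_baseline >= th, , drop = FALSE]
    a <- sub$delta_roa[sub$arm == "placebo"]
    b <- sub$delta_roa[sub$arm == "bvitamin"]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(boot_p_mean = NA_real_, boot_p_lo = NA_real_,
                        boot_p_hi = NA_real_, hedges_g = NA_real_,
                        hedges_g_abs = NA_real_, effect_class = NA_character_,
                        stringsAsFactors = FALSE))
    }
    bp <- bootstrap_group_p(a, b, n_boot = config$n_boot, m = config$m,
                            seed = child_seed(config$seed, i))
    eff <- tryCatch(hedges_g(a, b), error = function(e) list(g = NA_real_))
    data.frame(boot_p_mean = bp$boot_p_mean,
               boot_p_lo = bp$boot_p_ci[1], boot_p_hi = bp$boot_p_ci[2],
               hedges_g = eff$g, hedges_g_abs = abs(eff$g),
               effect_class = classify_effect(eff$g),
               stringsAsFactors = FALSE)
  })
  out <- cbind(slopes, do.call(rbind, extra))
  class(out) <- c("sweep_result", class(out))
  out
}

#' First threshold at which the bootstrapped p-value crosses significance
#'
#' @param sweep a [run_threshold_sweep()] result.
#' @param alpha significance level, default 0.05.
#' @return The smallest threshold with `boot_p_mean < alpha`, or `NA` if
#'   none.
#' @export
first_significant_threshold <- function(sweep, alpha = 0.05) {
  hit <- which(!is.na(sweep$boot_p_mean) & sweep$boot_p_mean < alpha)
  if (length(hit) == 0L) return(NA_real_)
  sweep$threshold[hit[1L]]
}
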