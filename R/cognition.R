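#' Huber robust simple linear regression
#'
#' M-estimation by iteratively reweighted least squares with the Huber psi
#' function (tuning constant 1.345 on standardized residuals) and scale
#' estimated from the median absolute deviation of the residuals at each
#' iteration. Iterates until the coefficient change falls below `tol`
#' (1e-8) or `max_iter` (50) iterations, returning the last iterate with a
#' `converged` flag.
#'
#' When every standardized residual of the OLS fit falls below the tuning
#' constant, all weights are 1 and the result equals OLS exactly.
#'
#' @param x,y numeric vectors, `n >= 5`, `x` non-constant.
#' @param k Huber tuning constant, default 1.345.
#' @param tol convergence tolerance on the coefficient change, default 1e-8.
#' @param max_iter iteration cap, default 50.
#' @return A list: `slope`, `intercept`, `slope_se`, `iterations`,
#'   `converged`, `weights`.
#' @export
robust_regression <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 50L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant; regression undefined", call. = FALSE)
  X <- cbind(1, x)
  beta <- stats::coef(stats::lm.fit(X, y))
  w <- rep(1, n)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    r <- as.numeric(y - X %*% beta)
    s <- stats::mad(r, center = 0)
    if (s == 0) { converged <- TRUE; break } # exact fit
    u <- abs(r) / s
    w <- ifelse(u <= k, 1, k / u)
    fit <- stats::lm.wfit(X, y, w)
    delta <- max(abs(stats::coef(fit) - beta))
    beta <- stats::coef(fit)
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) warning("robust regression did not converge; returning last iterate")
  # sandwich-free SE on the weighted normal equations (classical IRLS SE)
  r <- as.numeric(y - X %*% beta)
  s2 <- sum(w * r^2) / (sum(w) - 2)
  XtWX <- crossprod(X * sqrt(w))
  se <- sqrt(diag(s2 * solve(XtWX)))
  list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
       slope_se = unname(se[2L]), iterations = iter, converged = converged,
       weights = w)
}

#' Partial correlation by double residualization
#'
#' Residualizes both `x` and `y` on the covariate `z` by OLS and correlates
#' the residuals. Algebraically identical to the closed-form first-order
#' partial correlation
#' `(r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2) * (1 - r_zy^2))`.
#' The p-value uses `n - 3` degrees of freedom (one lost to the covariate).
#'
#' @param x,y,z numeric vectors of equal length.
#' @return A list: `r`, `p`, `n`, and the residual vectors `x_res`, `y_res`.
#' @export
partial_correlation <- function(x, y, z) {
  keep <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete observations", call. = FALSE)
  xr <- stats::residuals(stats::lm(x ~ z))
  yr <- stats::residuals(stats::lm(y ~ z))
  r <- stats::cor(xr, yr)
  tstat <- r * sqrt(n - 3) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 3), n = n,
       x_res = as.numeric(xr), y_res = as.numeric(yr))
}

#' Associate the two-year ROA change with baseline cognitive scores
#'
#' Per arm and cognitive test: the Pearson correlation (and two-sided p) of
#' the baseline score with the two-year ROA change, together with the Huber
#' robust regression slope of the change on the score. With
#' `adjust_for_thcy = TRUE` both variables are residualized on baseline
#' tHcy first (partial correlation by double residualization; p on `n - 3`
#' degrees of freedom) — the "normalizing to baseline tHcy" adjustment.
#' Missing scores are pairwise-deleted per test; arm/test combinations with
#' fewer than `min_n` complete pairs are omitted with a logged count.
#'
#' @param cohort sample sheet with `subject_id`, `arm`, `thcy_baseline` and
#'   one column per cognitive test.
#' @param deltas data.frame with `subject_id` and `delta_roa` (single
#'   clock).
#' @param tests character vector of cognitive-test column names.
#' @param adjust_for_thcy residualize on baseline tHcy before correlating.
#' @param min_n minimum complete pairs per arm/test, default 5.
#' @return A data.frame: `test`, `arm`, `adjusted`, `n`, `r`, `p`,
#'   `robust_slope`, `robust_slope_se`.
#' @export
cognition_associations <- function(cohort, deltas, tests,
                                   adjust_for_thcy = FALSE, min_n = 5L) {
  missing_tests <- setdiff(tests, names(cohort))
  if (length(missing_tests) > 0L) {
    stop(sprintf("cohort lacks cognitive column(s): %s",
                 paste(missing_tests, collapse = ", ")), call. = FALSE)
  }
  d <- merge(cohort, deltas[, c("subject_id", "delta_roa")], by = "subject_id")
  skipped <- 0L
  rows <- list()
  for (arm in unique(d$arm)) {
    da <- d[d$arm == arm, , drop = FALSE]
    for (test in tests) {
      score <- da[[test]]
      keep <- is.finite(score) & is.finite(da$delta_roa) &
        (!adjust_for_thcy | is.finite(da$thcy_baseline))
      if (sum(keep) < min_n) { skipped <- skipped + 1L; next }
      s <- score[keep]; y <- da$delta_roa[keep]
      if (adjust_for_thcy) {
        pc <- partial_correlation(s, y, da$thcy_baseline[keep])
        r <- pc$r; p <- pc$p
        rob <- robust_regression(pc$x_res, pc$y_res)
      } else {
        r <- stats::cor(s, y)
        p <- pearson_pvalue(r, length(s))
        rob <- robust_regression(s, y)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        test = test, arm = arm, adjusted = adjust_for_thcy, n = length(s),
        r = r, p = p, robust_slope = rob$slope,
        robust_slope_se = rob$slope_se, stringsAsFactors = FALSE)
    }
  }
  log_exclusion(skipped, "arm/test combination(s) with insufficient data")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
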