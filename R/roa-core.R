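#' Rate of aging
#'
#' ROA is epigenetic age divided by chronological age. Rate-type clocks
#' (pace-of-aging) already output a rate, which is passed through
#' unchanged.
#'
#' @param epigenetic_age epigenetic age in years, or a rate for rate clocks.
#' @param chron_age chronological age in years (> 0); ignored when
#'   `is_rate = TRUE`.
#' @param is_rate logical flag; `TRUE` passes the clock output through.
#' @return Unitless ROA (vectorized).
#' @export
compute_roa <- function(epigenetic_age, chron_age, is_rate = FALSE) {
  if (isTRUE(is_rate)) return(epigenetic_age)
  if (any(!is.finite(chron_age)) || any(chron_age <= 0)) {
    stop("chronological age must be positive", call. = FALSE)
  }
  epigenetic_age / chron_age
}

#' Two-year change in ROA
#'
#' Follow-up ROA minus baseline ROA. Positive change indicates accelerated
#' aging over the interval; negative change, deceleration.
#'
#' @param roa_t2,roa_t1 follow-up and baseline ROA.
#' @return `roa_t2 - roa_t1` (vectorized).
#' @export
delta_roa <- function(roa_t2, roa_t1) roa_t2 - roa_t1

#' Simple linear regression with Pearson correlation
#'
#' Ordinary least squares of `y` on `x` together with the Pearson
#' correlation and its two-sided p-value from the t transform with `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, finite, with `x`
#'   non-constant.
#' @return A one-row data.frame: `slope`, `intercept`, `slope_se`,
#'   `residual_se`, `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant; regression undefined", call. = FALSE)
  if (stats::sd(y) == 0) stop("`y` is constant; correlation undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r <- stats::cor(x, y)
  data.frame(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             slope_se = sm$coefficients[2L, 2L],
             residual_se = sm$sigma,
             r = r,
             r_squared = r^2,
             p_value = pearson_pvalue(r, n),
             n = n)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' on `n - 2` degrees of freedom. `|r| = 1` returns `p = 0` by convention.
#'
#' @param r Pearson correlation, `|r| <= 1`.
#' @param n number of paired observations, `>= 3`.
#' @return Two-sided p-value.
#' @export
pearson_pvalue <- function(r, n) {
  check_scalar(r, "r"); check_scalar(n, "n")
  if (abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Two-sample t test (unpaired Welch / pooled, or paired)
#'
#' Unpaired comparisons default to the Welch statistic with
#' Welch–Satterthwaite degrees of freedom; a pooled-variance variant is
#' available for sensitivity checks. Paired comparisons test the mean
#' difference against its standard error. Degenerate inputs follow fixed
#' conventions: identical constant groups give `t = 0, p = 1`; a paired
#' difference with zero variance is an error.
#'
#' @param a,b numeric vectors; equal length when `paired = TRUE`.
#' @param paired logical.
#' @param var_equal use the pooled-variance statistic (unpaired only).
#' @return A list with `t`, `p`, `df`.
#' @export
group_ttest <- function(a, b, paired = FALSE, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (paired) {
    if (length(a) != length(b)) stop("paired test needs equal lengths", call. = FALSE)
    if (length(a) < 2L) stop("need n >= 2", call. = FALSE)
    d <- a - b
    if (stats::sd(d) == 0) {
      if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1))
      stop("paired differences have zero variance; test degenerate", call. = FALSE)
    }
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group", call. = FALSE)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
      stop("both groups constant with unequal means; test degenerate", call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Subset a cohort by baseline homocysteine
#'
#' Retains subjects whose *baseline* tHcy satisfies
#' `min_thcy <= thcy_baseline < max_thcy` (lower bound inclusive, upper
#' exclusive, matching the clinical conventions "≥ 15" and "< 15").
#'
#' @param cohort data.frame with a `thcy_baseline` column (a sample sheet).
#' @param min_thcy,max_thcy bounds in micromol/L; `NULL` leaves that side
#'   unbounded.
#' @return The filtered cohort.
#' @export
subgroup_by_thcy <- function(cohort, min_thcy = NULL, max_thcy = NULL) {
  if (!"thcy_baseline" %in% names(cohort)) {
    stop("cohort lacks a `thcy_baseline` column", call. = FALSE)
  }
  if (anyNA(cohort$thcy_baseline)) {
    stop("baseline tHcy must be defined for every subject", call. = FALSE)
  }
  if (!is.null(min_thcy) && !is.null(max_thcy) && min_thcy > max_thcy) {
    stop("`min_thcy` exceeds `max_thcy`", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(min_thcy)) keep <- keep & cohort$thcy_baseline >= min_thcy
  if (!is.null(max_thcy)) keep <- keep & cohort$thcy_baseline < max_thcy
  cohort[keep, , drop = FALSE]
}

#' Per-subject ROA table across clocks
#'
#' Evaluates each clock on the baseline and follow-up beta matrices, joins
#' chronological ages from the sample sheet, and derives ROA at both
#' timepoints plus the two-year change. Subjects missing either timepoint
#' for a clock are dropped from the change column with a logged count.
#'
#' @param cohort sample sheet (`subject_id`, `arm`, `age_baseline`,
#'   `age_followup`, ...). Subject ids must match beta matrix columns.
#' @param beta_t1,beta_t2 beta matrices at baseline / follow-up, columns
#'   named by subject id.
#' @param clocks list of [clock_definition()] objects.
#' @param allow_missing passed to [evaluate_clock()].
#' @return A data.frame: `subject_id`, `clock`, `epigenetic_age_t1`,
#'   `epigenetic_age_t2`, `roa_t1`, `roa_t2`, `delta_roa`.
#' @export
build_roa_table <- function(cohort, beta_t1, beta_t2, clocks,
                            allow_missing = FALSE) {
  if (inherits(clocks, "clock_definition")) clocks <- list(clocks)
  ids <- cohort$subject_id
  miss1 <- setdiff(ids, colnames(beta_t1))
  miss2 <- setdiff(ids, colnames(beta_t2))
  use <- setdiff(ids, union(miss1, miss2))
  log_exclusion(length(ids) - length(use),
                "subject(s) lacking methylation at both timepoints")
  co <- cohort[match(use, cohort$subject_id), ]
  out <- lapply(clocks, function(ck) {
    e1 <- evaluate_clock(beta_t1[, use, drop = FALSE], ck, allow_missing = allow_missing)
    e2 <- evaluate_clock(beta_t2[, use, drop = FALSE], ck, allow_missing = allow_missing)
    is_rate <- isTRUE(attr(e1, "is_rate"))
    r1 <- compute_roa(as.numeric(e1), co$age_baseline, is_rate)
    r2 <- compute_roa(as.numeric(e2), co$age_followup, is_rate)
    data.frame(subject_id = use, clock = ck$name,
               epigenetic_age_t1 = as.numeric(e1),
               epigenetic_age_t2 = as.numeric(e2),
               roa_t1 = r1, roa_t2 = r2,
               delta_roa = delta_roa(r2, r1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Baseline tHcy–ROA correlation per clock
#'
#' For each clock, regresses baseline ROA on baseline tHcy across the whole
#' cohort and reports the Pearson correlation, slope and p-value.
#'
#' @param roa_table output of [build_roa_table()].
#' @param cohort sample sheet with `thcy_baseline`.
#' @return A data.frame with one row per clock.
#' @export
baseline_roa_correlations <- function(roa_table, cohort) {
  res <- lapply(split(roa_table, roa_table$clock), function(d) {
    thcy <- cohort$thcy_baseline[match(d$subject_id, cohort$subject_id)]
    fit <- pearson_regression(thcy, d$roa_t1)
    cbind(clock = d$clock[1], fit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-clock group comparison of ROA (baseline/follow-up summary)
#'
#' Arm means and SDs of ROA at both timepoints plus between-arm (unpaired)
#' and within-arm (paired) two-tailed tests, per clock.
#'
#' @param roa_table output of [build_roa_table()].
#' @param cohort sample sheet with `arm` in `{placebo, bvitamin}`.
#' @return A data.frame with one row per clock.
#' @export
roa_group_summary <- function(roa_table, cohort) {
  res <- lapply(split(roa_table, roa_table$clock), function(d) {
    arm <- cohort$arm[match(d$subject_id, cohort$subject_id)]
    p1 <- d[arm == "placebo", ]; b1 <- d[arm == "bvitamin", ]
    data.frame(
      clock = d$clock[1],
      roa_t1_placebo_mean = mean(p1$roa_t1), roa_t1_placebo_sd = stats::sd(p1$roa_t1),
      roa_t1_bvitamin_mean = mean(b1$roa_t1), roa_t1_bvitamin_sd = stats::sd(b1$roa_t1),
      roa_t2_placebo_mean = mean(p1$roa_t2), roa_t2_placebo_sd = stats::sd(p1$roa_t2),
      roa_t2_bvitamin_mean = mean(b1$roa_t2), roa_t2_bvitamin_sd = stats::sd(b1$roa_t2),
      p_intergroup_t1 = group_ttest(p1$roa_t1, b1$roa_t1)$p,
      p_intergroup_t2 = group_ttest(p1$roa_t2, b1$roa_t2)$p,
      p_intragroup_placebo = group_ttest(p1$roa_t2, p1$roa_t1, paired = TRUE)$p,
      p_intragroup_bvitamin = group_ttest(b1$roa_t2, b1$roa_t1, paired = TRUE)$p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
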