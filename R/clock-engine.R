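#' Raw linear clock predictor
#'
#' Computes the affine score `intercept + sum_j weight_j * beta[j, s]` per
#' sample. Probes listed in the clock but absent from `beta` are an error
#' unless `allow_missing = TRUE`, in which case the missing terms are
#' dropped and the full intercept retained (truncated evaluation, as used
#' when validating clocks against arrays that lack some of their CpGs).
#' `NA` beta values at present probes are imputed probe-wise from
#' `reference` (by default the matrix itself) and the imputation count is
#' reported via `message()`.
#'
#' @param beta a [beta_matrix()] (or probes x samples matrix with dimnames).
#' @param clock a [clock_definition()]; its `pc_block` is ignored here (see
#'   [evaluate_clock()] for PC projection).
#' @param allow_missing drop missing-probe terms instead of erroring.
#' @param reference optional beta matrix supplying probe-wise means for
#'   imputation of `NA` values.
#' @return Named numeric vector of raw scores, one per sample.
#' @export
linear_predictor <- function(beta, clock, allow_missing = FALSE,
                             reference = NULL) {
  w <- clock$weights
  present <- names(w) %in% rownames(beta)
  if (!all(present)) {
    if (!allow_missing) {
      miss <- names(w)[!present]
      stop(sprintf("clock '%s': %d probe(s) missing from beta matrix: %s",
                   clock$name, length(miss),
                   paste(utils::head(miss, 5L), collapse = ", ")),
           call. = FALSE)
    }
    w <- w[present]
  }
  if (length(w) == 0L) {
    return(stats::setNames(rep(clock$intercept, ncol(beta)), colnames(beta)))
  }
  b <- impute_beta(beta[names(w), , drop = FALSE], reference)
  drop(clock$intercept + crossprod(b, w)[, 1L])
}

# Probe-wise mean imputation of NA betas; reference defaults to the matrix
# itself so the predictor stays defined without shifting scale.
impute_beta <- function(b, reference = NULL) {
  nas <- is.na(b)
  if (!any(nas)) return(b)
  ref <- if (is.null(reference)) b else reference[rownames(b), , drop = FALSE]
  mu <- rowMeans(ref, na.rm = TRUE)
  idx <- which(nas, arr.ind = TRUE)
  b[nas] <- mu[idx[, 1L]]
  message(sprintf("epiroa: imputed %d missing beta value(s) by probe mean", sum(nas)))
  b
}

#' Anti-transform of the log-linear age scale
#'
#' First-generation chronological-age clocks are fit on a transformed age
#' that is logarithmic below an adulthood constant and linear above it.
#' This maps a raw score back to years:
#' `age = (adult_age + 1) * exp(raw) - 1` for `raw < 0`, and
#' `age = raw * (adult_age + 1) + adult_age` otherwise. The map is strictly
#' increasing, continuous at `raw = 0` (both branches give `adult_age`),
#' and bounded below by -1.
#'
#' @param raw numeric vector of raw scores.
#' @param adult_age adulthood constant in years (> 0), default 20.
#' @return Epigenetic ages in years.
#' @export
horvath_age_inverse <- function(raw, adult_age = 20) {
  check_scalar(adult_age, "adult_age")
  if (adult_age <= 0) stop("`adult_age` must be > 0", call. = FALSE)
  ifelse(raw < 0, (adult_age + 1) * exp(raw) - 1, raw * (adult_age + 1) + adult_age)
}

# Forward transform (years -> raw); used by the simulator to construct
# clocks whose calibrated target lives in the transformed space.
horvath_age_forward <- function(age, adult_age = 20) {
  ifelse(age <= adult_age, log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' Evaluate an epigenetic clock on a beta matrix
#'
#' Applies the clock's architecture end to end: for plain clocks the linear
#' predictor followed by the output transform; for PC clocks the betas are
#' centered probe-wise, projected onto the loadings, and the component
#' scores combined with the component weights and intercept before the
#' transform.
#'
#' @inheritParams linear_predictor
#' @return Named numeric vector of epigenetic ages in years, or unitless
#'   rates for `transform = "rate"` clocks (attribute `is_rate` is set to
#'   `TRUE` in that case).
#' @export
evaluate_clock <- function(beta, clock, allow_missing = FALSE,
                           reference = NULL) {
  if (is.null(clock$pc_block)) {
    raw <- linear_predictor(beta, clock, allow_missing = allow_missing,
                            reference = reference)
  } else {
    pc <- clock$pc_block
    probes <- rownames(pc$loadings)
    present <- probes %in% rownames(beta)
    if (!all(present)) {
      stop(sprintf("pc clock '%s': %d probe(s) missing from beta matrix",
                   clock$name, sum(!present)), call. = FALSE)
    }
    b <- impute_beta(beta[probes, , drop = FALSE], reference)
    centered <- b - pc$centers
    scores <- crossprod(pc$loadings, centered)       # components x samples
    raw <- drop(clock$intercept + crossprod(scores, pc$component_weights)[, 1L])
    names(raw) <- colnames(beta)
  }
  out <- switch(clock$transform,
                identity = raw,
                horvath_age = horvath_age_inverse(raw, clock$adult_age),
                rate = raw)
  attr(out, "is_rate") <- clock$transform == "rate"
  out
}

#' Assess a clock truncated by missing probes
#'
#' When an array lacks some of a clock's CpGs, the clock can still be run
#' by dropping the missing terms. This quantifies how much of the full
#' predictor's signal survives: the Pearson correlation, across reference
#' samples, between the full predictor and the truncated predictor. Clocks
#' are included in downstream analyses only when that correlation is at
#' least `r_min` (0.9 by default); the associated signal loss is
#' `(1 - r^2) * 100` percent.
#'
#' @param clock a [clock_definition()] (plain linear clocks only).
#' @param available_probes character vector of probes present on the array.
#' @param reference_beta a beta matrix containing *all* clock probes for at
#'   least 3 samples, on which the two predictors are compared.
#' @param r_min inclusion gate on the overlap correlation, default 0.9.
#' @return A one-row data.frame: `clock`, `n_defined`, `n_missing`,
#'   `overlap_r`, `signal_loss_pct` (full precision),
#'   `signal_loss_pct_int` (integer-truncated, for display), `included`,
#'   and `note` (diagnostic for degenerate cases).
#' @export
truncation_overlap <- function(clock, available_probes, reference_beta,
                               r_min = 0.9) {
  probes <- names(clock$weights)
  if (!all(probes %in% rownames(reference_beta))) {
    stop("reference beta matrix must contain every clock probe", call. = FALSE)
  }
  if (ncol(reference_beta) < 3L) {
    stop("need at least 3 reference samples", call. = FALSE)
  }
  kept <- intersect(probes, available_probes)
  full <- linear_predictor(reference_beta, clock)
  trunc_clock <- clock
  trunc_clock$weights <- clock$weights[kept]
  truncated <- if (length(kept) == 0L) {
    rep(clock$intercept, ncol(reference_beta))
  } else {
    linear_predictor(reference_beta, trunc_clock)
  }
  note <- ""
  if (stats::sd(full) == 0 || stats::sd(truncated) == 0) {
    r <- NA_real_
    note <- "zero variance in a predictor; overlap correlation undefined"
  } else {
    r <- stats::cor(full, truncated)
  }
  loss <- (1 - r^2) * 100
  data.frame(
    clock = clock$name,
    n_defined = length(probes),
    n_missing = length(probes) - length(kept),
    overlap_r = r,
    signal_loss_pct = loss,
    signal_loss_pct_int = trunc(loss),
    included = !is.na(r) && r >= r_min,
    note = note,
    stringsAsFactors = FALSE)
}

#' Signal loss implied by a truncation overlap correlation
#'
#' The share of the full predictor's variance lost when only the truncated
#' predictor is observed: `(1 - r^2) * 100` percent. With
#' `integer_truncate = TRUE` the value is truncated toward zero for
#' display (an overlap of r = 0.901 reads as an 18 percent loss).
#'
#' @param r overlap correlation in `[-1, 1]`.
#' @param integer_truncate truncate to a whole percent.
#' @return Percent signal loss.
#' @export
signal_loss_pct <- function(r, integer_truncate = FALSE) {
  loss <- (1 - r^2) * 100
  if (integer_truncate) trunc(loss) else loss
}

#' Truncation reports for a set of clocks
#'
#' Convenience wrapper running [truncation_overlap()] per clock against the
#' probes present on an array.
#'
#' @param clocks list of [clock_definition()] objects.
#' @param available_probes probes present on the target array.
#' @param reference_beta reference beta matrix covering all clock probes.
#' @param r_min inclusion gate, default 0.9.
#' @return A data.frame with one row per clock.
#' @export
truncation_report <- function(clocks, available_probes, reference_beta,
                              r_min = 0.9) {
  do.call(rbind, lapply(clocks, truncation_overlap,
                        available_probes = available_probes,
                        reference_beta = reference_beta, r_min = r_min))
}
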