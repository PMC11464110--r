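#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed from a master seed
#'
#' Child seeds decouple the random streams of pipeline stages (and of the
#' per-threshold bootstraps within a sweep) from one another, so adding a
#' stage or a threshold never shuffles the draws of earlier ones. The map is
#' a fixed affine congruence on the 31-bit integer range.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m) + 1
  # two rounds of a multiplicative congruential step keep streams apart
  # even for adjacent (master, index) pairs
  s <- (s * 48271) %% m
  s <- (s + (index + 1) * 16807) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}

# Validate a numeric scalar argument; used throughout the public surface.
check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Small helper for logged exclusions: emits a message and returns the count
# so callers can reconcile input vs output row totals.
log_exclusion <- function(n, what) {
  if (n > 0) message(sprintf("epiroa: excluded %d %s", n, what))
  invisible(n)
}
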