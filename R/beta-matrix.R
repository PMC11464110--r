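#' Construct a beta-value matrix
#'
#' A beta matrix holds CpG methylation fractions (beta values, the fraction
#' of methylated signal at a locus) as probes x samples. Values must lie in
#' `[0, 1]`; missing measurements are `NA`.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids,sample_ids optional character vectors; default to the
#'   dimnames of `values`.
#' @return A numeric matrix of class `beta_matrix` with unique row and
#'   column names.
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe and sample identifiers are required", call. = FALSE)
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta values must lie in [0, 1] (or be NA)", call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' Read a beta matrix from delimited text
#'
#' Expects a CSV whose first column holds probe ids and whose remaining
#' columns are samples; empty cells are treated as missing.
#'
#' @param path file path.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("beta matrix file needs a probe column and at least one sample", call. = FALSE)
  probes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  beta_matrix(m, probe_ids = probes, sample_ids = colnames(df)[-1L])
}

#' Write a beta matrix to delimited text
#'
#' @param beta a [beta_matrix()] (or plain named matrix).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), unclass(beta),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
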