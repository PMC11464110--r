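#' Define an epigenetic clock
#'
#' An epigenetic clock is a linear predictor over CpG beta values with an
#' output transform. Three transforms are supported:
#' \describe{
#'   \item{`identity`}{the raw affine score is the epigenetic age (years).}
#'   \item{`horvath_age`}{the raw score lives in the log-linear transformed
#'     age space used by first-generation chronological-age clocks and is
#'     mapped back to years by [horvath_age_inverse()].}
#'   \item{`rate`}{the clock outputs a pace of aging directly (unitless
#'     rate, DunedinPACE-style); downstream ROA code passes it through
#'     without dividing by chronological age.}
#' }
#' A clock may additionally carry a principal-component block: betas are
#' centered probe-wise, projected onto loadings, and the component scores
#' are combined with `component_weights` before the intercept is added.
#'
#' @param name clock label.
#' @param weights named numeric vector of probe coefficients (probe ids as
#'   names; for PC clocks these are the `component_weights` and may be
#'   supplied via `pc_block` instead).
#' @param intercept numeric intercept.
#' @param transform one of `"identity"`, `"horvath_age"`, `"rate"`.
#' @param adult_age adulthood constant (years) used only by the
#'   `horvath_age` transform; default 20.
#' @param pc_block optional list with elements `loadings` (probes x
#'   components matrix with dimnames), `centers` (named numeric, per probe)
#'   and `component_weights` (named numeric, per component).
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(name, weights, intercept = 0,
                             transform = c("identity", "horvath_age", "rate"),
                             adult_age = 20, pc_block = NULL) {
  transform <- match.arg(transform)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(weights) == 0L) stop("`weights` must be non-empty", call. = FALSE)
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("`weights` must be named by probe id", call. = FALSE)
  }
  if (anyDuplicated(names(weights))) {
    stop("duplicate probe ids in `weights`", call. = FALSE)
  }
  check_scalar(intercept, "intercept")
  check_scalar(adult_age, "adult_age")
  if (transform == "horvath_age" && adult_age <= 0) {
    stop("`adult_age` must be positive for the horvath_age transform", call. = FALSE)
  }
  if (!is.null(pc_block)) {
    pc_block <- validate_pc_block(pc_block)
  }
  structure(
    list(name = name, weights = weights, intercept = intercept,
         transform = transform, adult_age = adult_age, pc_block = pc_block),
    class = "clock_definition"
  )
}

validate_pc_block <- function(pc_block) {
  need <- c("loadings", "centers", "component_weights")
  if (!all(need %in% names(pc_block))) {
    stop("`pc_block` needs loadings, centers and component_weights", call. = FALSE)
  }
  L <- pc_block$loadings
  if (!is.matrix(L) || is.null(rownames(L)) || is.null(colnames(L))) {
    stop("pc loadings must be a matrix with probe rownames and component colnames",
         call. = FALSE)
  }
  ctr <- pc_block$centers
  if (!setequal(rownames(L), names(ctr))) {
    stop("pc loadings probe set must equal centers probe set", call. = FALSE)
  }
  cw <- pc_block$component_weights
  if (!setequal(colnames(L), names(cw))) {
    stop("component_weights must be named by the loading columns", call. = FALSE)
  }
  pc_block$centers <- ctr[rownames(L)]
  pc_block$component_weights <- cw[colnames(L)]
  pc_block
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("<clock_definition> %s: %d probes, transform = %s%s\n",
              x$name,
              if (is.null(x$pc_block)) length(x$weights) else nrow(x$pc_block$loadings),
              x$transform,
              if (is.null(x$pc_block)) "" else
                sprintf(", %d principal components", ncol(x$pc_block$loadings))))
  invisible(x)
}

# Probe ids a clock needs from a beta matrix.
clock_probes <- function(clock) {
  if (is.null(clock$pc_block)) names(clock$weights) else rownames(clock$pc_block$loadings)
}

#' Read clock definitions from a coefficient table
#'
#' The coefficient table is long-format CSV with columns
#' `clock,probe,weight`. Per-clock metadata travel as pseudo-probe rows:
#' `__intercept__`, `__transform__` and `__adult_age__`. Principal-component
#' blocks live in companion CSVs next to the table, named
#' `<stem>_<clock>_loadings.csv` (probe x component, first column `probe`),
#' `<stem>_<clock>_centers.csv` (`probe,value`) and
#' `<stem>_<clock>_components.csv` (`component,value`); for PC clocks the
#' main table's weight rows are ignored in favour of the component weights.
#'
#' @param path coefficient table file.
#' @return A named list of [clock_definition()] objects.
#' @seealso [write_clock_definitions()] for the round-trip writer.
#' @export
read_clock_definitions <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  if (!identical(names(df)[1:3], c("clock", "probe", "weight"))) {
    stop("coefficient table must have columns clock,probe,weight", call. = FALSE)
  }
  if (anyDuplicated(df[, c("clock", "probe")])) {
    dup <- df[duplicated(df[, c("clock", "probe")]), ]
    stop(sprintf("duplicate (clock, probe) pair: %s/%s",
                 dup$clock[1], dup$probe[1]), call. = FALSE)
  }
  stem <- sub("\\.[^.]*$", "", path)
  out <- lapply(split(df, df$clock), function(d) {
    nm <- d$clock[1]
    meta <- startsWith(d$probe, "__")
    md <- stats::setNames(d$weight[meta], d$probe[meta])
    transform <- unname(md["__transform__"])
    if (is.na(transform)) transform <- "identity"
    if (!transform %in% c("identity", "horvath_age", "rate")) {
      stop(sprintf("unknown transform label '%s' for clock '%s'", transform, nm),
           call. = FALSE)
    }
    intercept <- if (is.na(md["__intercept__"])) 0 else as.numeric(md["__intercept__"])
    adult_age <- if (is.na(md["__adult_age__"])) 20 else as.numeric(md["__adult_age__"])
    w <- d[!meta, , drop = FALSE]
    weights <- stats::setNames(as.numeric(w$weight), w$probe)
    pc <- read_pc_block(stem, nm)
    if (!is.null(pc)) weights <- pc$component_weights
    clock_definition(nm, weights, intercept = intercept, transform = transform,
                     adult_age = adult_age, pc_block = pc)
  })
  out[order(names(out))]
}

read_pc_block <- function(stem, clock_name) {
  fl <- sprintf("%s_%s_loadings.csv", stem, clock_name)
  if (!file.exists(fl)) return(NULL)
  ld <- utils::read.csv(fl, check.names = FALSE, stringsAsFactors = FALSE)
  L <- as.matrix(ld[, -1L, drop = FALSE])
  rownames(L) <- ld[[1L]]
  ctr <- utils::read.csv(sprintf("%s_%s_centers.csv", stem, clock_name),
                         stringsAsFactors = FALSE)
  cw <- utils::read.csv(sprintf("%s_%s_components.csv", stem, clock_name),
                        stringsAsFactors = FALSE)
  list(loadings = L,
       centers = stats::setNames(ctr$value, ctr$probe),
       component_weights = stats::setNames(cw$value, cw$component))
}

#' Write clock definitions to a coefficient table
#'
#' Inverse of [read_clock_definitions()]; PC blocks are written to the
#' companion CSVs described there.
#'
#' @param clocks a [clock_definition()] or list of them.
#' @param path destination coefficient table.
#' @return `path`, invisibly.
#' @export
write_clock_definitions <- function(clocks, path) {
  if (inherits(clocks, "clock_definition")) clocks <- list(clocks)
  stem <- sub("\\.[^.]*$", "", path)
  rows <- lapply(clocks, function(ck) {
    meta <- data.frame(
      clock = ck$name,
      probe = c("__intercept__", "__transform__", "__adult_age__"),
      weight = c(format(ck$intercept, digits = 17), ck$transform,
                 format(ck$adult_age, digits = 17)),
      stringsAsFactors = FALSE)
    if (is.null(ck$pc_block)) {
      wt <- data.frame(clock = ck$name, probe = names(ck$weights),
                       weight = format(unname(ck$weights), digits = 17),
                       stringsAsFactors = FALSE)
      rbind(meta, wt)
    } else {
      pc <- ck$pc_block
      utils::write.csv(
        data.frame(probe = rownames(pc$loadings), pc$loadings, check.names = FALSE),
        sprintf("%s_%s_loadings.csv", stem, ck$name), row.names = FALSE)
      utils::write.csv(
        data.frame(probe = names(pc$centers), value = unname(pc$centers)),
        sprintf("%s_%s_centers.csv", stem, ck$name), row.names = FALSE)
      utils::write.csv(
        data.frame(component = names(pc$component_weights),
                   value = unname(pc$component_weights)),
        sprintf("%s_%s_components.csv", stem, ck$name), row.names = FALSE)
      meta
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
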