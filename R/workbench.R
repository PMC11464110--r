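#' Read and validate a sample sheet
#'
#' @param path CSV with columns `subject_id`, `arm`, `age_baseline`,
#'   `age_followup`, `thcy_baseline` (plus optional follow-up tHcy and
#'   cognitive-test columns).
#' @return A data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "age_baseline", "age_followup", "thcy_baseline")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$arm), c("placebo", "bvitamin"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown arm label(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids", call. = FALSE)
  df
}

#' Per-clock between-arm comparison of the two-year ROA change
#'
#' Restricts to subjects with baseline tHcy at or above `min_thcy` and, per
#' clock, reports arm means/SDs of the ROA change and the unpaired
#' two-tailed t-test p-value. Clocks whose subgroup leaves an arm empty (or
#' with one subject) are omitted with a logged count.
#'
#' @param roa_table a [build_roa_table()] result.
#' @param cohort sample sheet with `arm` and `thcy_baseline`.
#' @param min_thcy subgroup threshold in micromol/L (inclusive).
#' @return A data.frame with one row per clock.
#' @export
build_group_comparison <- function(roa_table, cohort, min_thcy = 13) {
  sub <- subgroup_by_thcy(cohort, min_thcy = min_thcy)
  if (nrow(sub) == 0L) {
    message(sprintf("epiroa: empty tHcy subgroup at min_thcy = %g", min_thcy))
    return(NULL)
  }
  d <- roa_table[roa_table$subject_id %in% sub$subject_id, , drop = FALSE]
  skipped <- 0L
  rows <- lapply(split(d, d$clock), function(dd) {
    arm <- sub$arm[match(dd$subject_id, sub$subject_id)]
    a <- dd$delta_roa[arm == "placebo"]
    b <- dd$delta_roa[arm == "bvitamin"]
    if (length(a) < 2L || length(b) < 2L) { skipped <<- skipped + 1L; return(NULL) }
    tt <- group_ttest(a, b)
    data.frame(clock = dd$clock[1], min_thcy = min_thcy,
               n_placebo = length(a), n_treated = length(b),
               delta_placebo_mean = mean(a), delta_placebo_sd = stats::sd(a),
               delta_treated_mean = mean(b), delta_treated_sd = stats::sd(b),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  log_exclusion(skipped, "clock(s) with an empty/degenerate tHcy subgroup")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a run manifest
#'
#' Records the configuration snapshot, input-file digests, seeds, package
#' version and per-stage row counts, so that identical manifests imply
#' identical outputs for the deterministic stages.
#'
#' @param config named list (configuration snapshot).
#' @param inputs character vector of input file paths (digested with MD5).
#' @param seed master seed.
#' @param counts named list/vector of per-stage row counts.
#' @param warnings character vector of accumulated warnings.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), inputs = character(), seed = NA_integer_,
                         counts = list(), warnings = character()) {
  digests <- if (length(inputs) > 0L) as.list(tools::md5sum(inputs)) else list()
  structure(list(
    config = config,
    input_digests = digests,
    seed = seed,
    package_version = as.character(utils::packageVersion("epiroa")),
    r_version = as.character(getRversion()),
    counts = counts,
    warnings = warnings,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else i <- i + 1L
  }
  opts
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line workbench
#'
#' Entry point for scripted runs:
#' `Rscript -e 'epiroa::epiroa_cli()' <command> [--options]` with commands
#' `simulate`, `clocks`, `roa`, `sweep`, `cognition`, `report`. Common
#' flags: `--out <dir>`, `--seed <int>`, `--sample-sheet`, `--beta-t1`,
#' `--beta-t2`, `--clocks <coefficient table>`; stage flags `--min-thcy`,
#' `--n-boot`, `--m`, `--clock <name>`, `--adjust-thcy`. Every stage writes
#' CSV outputs plus a JSON manifest into `--out` and returns (invisibly)
#' the exit status: 0 on success, 1 on validation failure. The workbench
#' orchestrates and validates only; all numerics live in the stage
#' functions.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisible integer exit status (also reported via [quit()] when
#'   run non-interactively).
#' @export
epiroa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L) stop("usage: epiroa_cli <simulate|clocks|roa|sweep|cognition|report> [--options]", call. = FALSE)
    cmd <- args[1L]
    opts <- cli_opts(args[-1L])
    out_dir <- opts[["out"]] %||% "."
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(cli_num(opts, "seed", 1))
    switch(cmd,
      simulate = cli_simulate(opts, out_dir, seed),
      clocks = cli_clocks(opts, out_dir),
      roa = cli_roa(opts, out_dir),
      sweep = cli_sweep(opts, out_dir, seed),
      cognition = cli_cognition(opts, out_dir),
      report = cli_report(opts, out_dir),
      stop(sprintf("unknown command '%s'", cmd), call. = FALSE))
    0L
  }, error = function(e) {
    message("epiroa error: ", conditionMessage(e))
    1L
  })
  if (!interactive()) quit(status = status, save = "no")
  invisible(status)
}

cli_inputs <- function(opts, keys) {
  for (k in keys) {
    if (is.null(opts[[k]])) stop(sprintf("missing required option --%s", gsub("_", "-", k)), call. = FALSE)
    if (!file.exists(opts[[k]])) stop(sprintf("no such file: %s", opts[[k]]), call. = FALSE)
  }
  invisible(TRUE)
}

cli_simulate <- function(opts, out_dir, seed) {
  cfg <- sim_config(seed = seed,
                    n_per_arm = as.integer(cli_num(opts, "n_per_arm", 110)))
  sim <- generate_cohort(cfg)
  paths <- write_cohort_bundle(sim, out_dir)
  write_manifest(run_manifest(config = unclass(cfg), inputs = unname(paths),
                              seed = seed,
                              counts = list(subjects = nrow(sim$cohort),
                                            probes = nrow(sim$beta_t1))),
                 file.path(out_dir, "manifest.json"))
}

cli_load_stage <- function(opts) {
  cli_inputs(opts, c("sample_sheet", "beta_t1", "beta_t2", "clocks"))
  cohort <- read_sample_sheet(opts[["sample_sheet"]])
  beta1 <- read_beta_matrix(opts[["beta_t1"]])
  beta2 <- read_beta_matrix(opts[["beta_t2"]])
  clocks <- read_clock_definitions(opts[["clocks"]])
  if (!is.null(opts[["clock"]])) {
    sel <- strsplit(opts[["clock"]], ",")[[1L]]
    unknown <- setdiff(sel, names(clocks))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown clock name(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
    }
    clocks <- clocks[sel]
  }
  missing_ids <- setdiff(cohort$subject_id, colnames(beta1))
  if (length(missing_ids) == nrow(cohort)) {
    stop("no sample-sheet subject ids found among beta matrix columns", call. = FALSE)
  }
  list(cohort = cohort, beta1 = beta1, beta2 = beta2, clocks = clocks,
       inputs = c(opts[["sample_sheet"]], opts[["beta_t1"]], opts[["beta_t2"]], opts[["clocks"]]))
}

cli_roa_table <- function(st) {
  build_roa_table(st$cohort, st$beta1, st$beta2, st$clocks)
}

cli_clocks <- function(opts, out_dir) {
  st <- cli_load_stage(opts)
  ages <- lapply(st$clocks, function(ck) {
    data.frame(subject_id = colnames(st$beta1), clock = ck$name,
               epigenetic_age_t1 = as.numeric(evaluate_clock(st$beta1, ck)),
               epigenetic_age_t2 = as.numeric(evaluate_clock(st$beta2, ck)),
               stringsAsFactors = FALSE)
  })
  ages <- do.call(rbind, ages)
  utils::write.csv(ages, file.path(out_dir, "epigenetic_ages.csv"), row.names = FALSE)
  plain <- Filter(function(ck) is.null(ck$pc_block), st$clocks)
  if (length(plain) > 0L) {
    tr <- truncation_report(plain, rownames(st$beta1), st$beta1)
    utils::write.csv(tr, file.path(out_dir, "truncation_report.csv"), row.names = FALSE)
  }
  write_manifest(run_manifest(inputs = st$inputs,
                              counts = list(age_rows = nrow(ages))),
                 file.path(out_dir, "manifest.json"))
}

cli_roa <- function(opts, out_dir) {
  st <- cli_load_stage(opts)
  roa <- cli_roa_table(st)
  utils::write.csv(roa, file.path(out_dir, "roa_table.csv"), row.names = FALSE)
  utils::write.csv(baseline_roa_correlations(roa, st$cohort),
                   file.path(out_dir, "baseline_correlations.csv"), row.names = FALSE)
  utils::write.csv(roa_group_summary(roa, st$cohort),
                   file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  write_manifest(run_manifest(inputs = st$inputs,
                              counts = list(roa_rows = nrow(roa))),
                 file.path(out_dir, "manifest.json"))
}

cli_deltas <- function(st, roa, clock_name) {
  d <- roa[roa$clock == clock_name, , drop = FALSE]
  idx <- match(d$subject_id, st$cohort$subject_id)
  data.frame(subject_id = d$subject_id,
             arm = st$cohort$arm[idx],
             thcy_baseline = st$cohort$thcy_baseline[idx],
             delta_roa = d$delta_roa, stringsAsFactors = FALSE)
}

cli_sweep <- function(opts, out_dir, seed) {
  st <- cli_load_stage(opts)
  roa <- cli_roa_table(st)
  clock_name <- names(st$clocks)[1L]
  cfg <- sweep_config(n_boot = as.integer(cli_num(opts, "n_boot", 1000)),
                      m = as.integer(cli_num(opts, "m", 50)), seed = seed)
  sweep <- run_threshold_sweep(cli_deltas(st, roa, clock_name), cfg)
  utils::write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  cmp <- build_group_comparison(roa, st$cohort,
                                min_thcy = cli_num(opts, "min_thcy", 13))
  utils::write.csv(cmp, file.path(out_dir, "group_comparison.csv"), row.names = FALSE)
  write_manifest(run_manifest(config = unclass(cfg), inputs = st$inputs,
                              seed = seed,
                              counts = list(thresholds = nrow(sweep))),
                 file.path(out_dir, "manifest.json"))
}

cli_cognition <- function(opts, out_dir) {
  st <- cli_load_stage(opts)
  roa <- cli_roa_table(st)
  clock_name <- names(st$clocks)[1L]
  deltas <- cli_deltas(st, roa, clock_name)
  tests <- intersect(cognitive_panel()$test, names(st$cohort))
  if (length(tests) == 0L) stop("sample sheet has no cognitive-test columns", call. = FALSE)
  res <- rbind(
    cognition_associations(st$cohort, deltas, tests, adjust_for_thcy = FALSE),
    if (isTRUE(opts[["adjust_thcy"]]))
      cognition_associations(st$cohort, deltas, tests, adjust_for_thcy = TRUE))
  utils::write.csv(res, file.path(out_dir, "cognition.csv"), row.names = FALSE)
  write_manifest(run_manifest(inputs = st$inputs,
                              counts = list(associations = nrow(res))),
                 file.path(out_dir, "manifest.json"))
}

cli_report <- function(opts, out_dir) {
  files <- c("baseline_correlations.csv", "group_summary.csv", "sweep.csv",
             "group_comparison.csv", "cognition.csv")
  lines <- c("# epiroa run report", "")
  for (f in files) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) next
    df <- utils::read.csv(p)
    lines <- c(lines, sprintf("## %s (%d rows)", f, nrow(df)), "",
               utils::capture.output(print(utils::head(df, 40))), "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
}
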