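# Small fixture builders shared across the suite. Everything is generated
# in code; no stored data files.

tiny_beta <- function(n_probes = 5, n_samples = 4, seed = 101) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples), n_probes, n_samples)
  beta_matrix(m,
              probe_ids = sprintf("cg%07d", seq_len(n_probes)),
              sample_ids = sprintf("S%02d", seq_len(n_samples)))
}

tiny_clock <- function(beta, seed = 202, intercept = 1.5,
                       transform = "identity") {
  set.seed(seed)
  clock_definition("tiny",
                   weights = stats::setNames(rnorm(nrow(beta)), rownames(beta)),
                   intercept = intercept, transform = transform)
}

# Deterministic two-arm delta table with a hinge treatment effect at tau.
hinge_deltas <- function(n_per_arm = 100, tau = 13, slope = 0.004,
                         reversal = -0.6, noise = 0, seed = 33) {
  set.seed(seed)
  thcy <- rlnorm(2 * n_per_arm, log(12) - 0.05, 0.32)
  arm <- rep(c("placebo", "bvitamin"), each = n_per_arm)
  s <- ifelse(arm == "placebo", slope, reversal * slope)
  data.frame(arm = arm, thcy_baseline = thcy,
             delta_roa = s * pmax(0, thcy - tau) + rnorm(2 * n_per_arm, 0, noise))
}

# Minimal sample sheet for workbench-level tests.
tiny_cohort <- function(n = 8) {
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             arm = rep(c("placebo", "bvitamin"), length.out = n),
             age_baseline = seq(72, by = 1, length.out = n),
             age_followup = seq(74, by = 1, length.out = n),
             thcy_baseline = seq(8, by = 1.5, length.out = n),
             stringsAsFactors = FALSE)
}
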