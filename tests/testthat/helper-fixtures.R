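# Shared fixtures, built in code. Expensive cohort runs are computed once
# per session and cached.

.fixtures <- new.env(parent = emptyenv())

# Beta maps over an n-vertex mask engineered so that after z-scoring over
# the mask, vertex 1 carries exactly the requested z value for each taste.
# The remaining vertices hold a fixed spread pattern; vertex 1's beta is
# found by root-finding on the standardization identity, so the fixture
# exercises the real zscore_maps() path.
toy_beta_fixture <- function(z_target, n = 101) {
  stopifnot(length(z_target) == 6, n >= 10)
  y <- scale(seq_len(n - 1))[, 1]           # fixed pattern, mean 0 sd 1
  beta <- sapply(z_target, function(a) {
    f <- function(x1) {
      v <- c(x1, y)
      (x1 - mean(v)) / stats::sd(v) - a
    }
    x1 <- stats::uniroot(f, c(-50, 50), tol = 1e-14)$root
    c(x1, y)
  })
  colnames(beta) <- taste_labels()
  beta
}

toy_zscore_fixture <- function(z_target, n = 101) {
  beta <- toy_beta_fixture(z_target, n)
  zscore_maps(beta, mask = rep(TRUE, n))
}

# Default synthetic cohort (10 subjects, 2 motion violators) analysed end
# to end; cached across test files.
default_run <- function() {
  if (is.null(.fixtures$default_run)) {
    cfg <- default_config(seed = 7)
    cohort <- simulate_cohort(cfg)
    res <- suppressMessages(run_pipeline(cohort, exclude_taste = "co2"))
    .fixtures$default_run <- list(cohort = cohort, res = res)
  }
  .fixtures$default_run
}

# Noiseless identity-warp cohort with the full chain run through the
# prevalence stage; cached.
noiseless_run <- function() {
  if (is.null(.fixtures$noiseless_run)) {
    cfg <- default_config(seed = 3, n_subjects = 3)
    cfg$noise <- list(sigma = 0, ar1_rho = 0, drift_amp = 0)
    cfg$warp$max_disp <- 0
    cfg$n_violators <- 0L
    cfg$glm$fwhm <- 0
    cohort <- simulate_cohort(cfg)
    # identical noiseless subjects make the group t stage degenerate
    # (zero across-subject variance is expected and logged); silence it
    res <- suppressMessages(suppressWarnings(
      run_pipeline(cohort, stop_after = "prevalence")))
    .fixtures$noiseless_run <- list(cohort = cohort, res = res)
  }
  .fixtures$noiseless_run
}

# Small patch reused by mesh-level tests.
small_patch <- function() {
  if (is.null(.fixtures$small_patch))
    .fixtures$small_patch <- make_template_patch(200, seed = 3)
  .fixtures$small_patch
}
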