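#' Build the GLM design matrix
#'
#' One boxcar regressor per taste, spanning the delivery plus tasting
#' phases (optionally also the swallow phase), convolved with the canonical
#' HRF and with its temporal derivative; cue, swallow and rinse-water
#' nuisance regressors convolved with the canonical HRF; the six motion
#' traces; discrete-cosine (DCT) drift regressors for every frequency below
#' `1 / hp_cutoff`; and a trailing intercept.
#'
#' @param schedule A `stim_schedule`.
#' @param hrf An `hrf_kernel`, see [canonical_hrf()].
#' @param motion Optional 6 x n_volumes matrix of motion traces (all-zero
#'   or `NULL` drops the motion columns).
#' @param hp_cutoff High-pass cutoff in seconds (DCT drift columns model
#'   all slower frequencies). A warning is issued if it would intrude on
#'   task frequencies (`hp_cutoff <= 2 * tr`).
#' @param include_swallow Should the taste boxcar extend over the swallow
#'   phase? Default `FALSE` (delivery + tasting only).
#' @param derivatives Include temporal-derivative columns for the tastes.
#' @return A `design_matrix`: `matrix` (n_volumes x p), `labels`,
#'   `taste_cols` (named indices of the canonical taste columns),
#'   `hp_cutoff`, `tr`.
#' @export
build_design_matrix <- function(schedule, hrf = canonical_hrf(),
                                motion = NULL, hp_cutoff = 128,
                                include_swallow = FALSE,
                                derivatives = TRUE) {
  tr <- schedule$tr
  n <- schedule$n_volumes
  if (hp_cutoff <= 2 * tr)
    warning("hp_cutoff <= 2 * TR: drift columns reach task frequencies")
  total <- schedule$total_duration
  times <- (seq_len(n) - 1) * tr
  timing <- schedule$timing
  taste_dur <- timing$delivery + timing$tasting +
    if (include_swallow) timing$swallow else 0

  cols <- list()
  labels <- character()

  for (tst in taste_labels()) {
    ev <- schedule_events(schedule, tst)
    assert_that(nrow(ev) > 0, "schedule has no events for taste '%s'", tst)
    cols[[length(cols) + 1L]] <- convolve_events(
      ev$onset, rep(taste_dur, nrow(ev)), hrf$values, hrf$dt, total, times)
    labels <- c(labels, tst)
  }
  if (derivatives) {
    for (tst in taste_labels()) {
      ev <- schedule_events(schedule, tst)
      cols[[length(cols) + 1L]] <- convolve_events(
        ev$onset, rep(taste_dur, nrow(ev)), hrf$derivative, hrf$dt, total, times)
      labels <- c(labels, paste0(tst, "_deriv"))
    }
  }
  for (nm in c("cue", "swallow")) {
    ev <- schedule_events(schedule, nm)
    cols[[length(cols) + 1L]] <- convolve_events(
      ev$onset, ev$duration, hrf$values, hrf$dt, total, times)
    labels <- c(labels, nm)
  }
  ev <- schedule_events(schedule, "water")
  cols[[length(cols) + 1L]] <- convolve_events(
    ev$onset, rep(taste_dur, nrow(ev)), hrf$values, hrf$dt, total, times)
  labels <- c(labels, "rinse")

  if (!is.null(motion) && any(motion != 0)) {
    assert_that(ncol(motion) == n,
                "motion traces must have %d columns, got %d", n, ncol(motion))
    m <- t(motion)
    m <- sweep(m, 2, colMeans(m))
    for (j in seq_len(ncol(m))) {
      cols[[length(cols) + 1L]] <- m[, j]
      labels <- c(labels, paste0("motion", j))
    }
  }

  D <- dct_basis(n, tr, hp_cutoff)
  if (ncol(D)) {
    for (j in seq_len(ncol(D))) cols[[length(cols) + 1L]] <- D[, j]
    labels <- c(labels, paste0("dct", seq_len(ncol(D))))
  }
  cols[[length(cols) + 1L]] <- rep(1, n)
  labels <- c(labels, "intercept")

  X <- do.call(cbind, cols)
  colnames(X) <- labels
  out <- list(matrix = X, labels = labels,
              taste_cols = stats::setNames(match(taste_labels(), labels),
                                           taste_labels()),
              hp_cutoff = hp_cutoff, tr = tr)
  class(out) <- "design_matrix"
  out
}

# Discrete cosine drift basis: k = 1 .. floor(2 * T_total / hp_cutoff),
# X_k(v) = cos(pi * k * (2v - 1) / (2n)); columns are mutually orthogonal
# over the n samples (the k = 0 term is the intercept and is excluded).
dct_basis <- function(n, tr, hp_cutoff) {
  k_max <- floor(2 * n * tr / hp_cutoff)
  v <- seq_len(n)
  if (k_max < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  sapply(seq_len(k_max), function(k) cos(pi * k * (2 * v - 1) / (2 * n)))
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d regressors (hp %g s)\n",
              nrow(x$matrix), ncol(x$matrix), x$hp_cutoff))
  invisible(x)
}
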