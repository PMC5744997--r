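#' Simulate head-motion parameter traces
#'
#' Bounded random walks for three translations (units of in-plane voxel
#' size) and three rotations (degrees). `"compliant"` traces stay strictly
#' inside the exclusion thresholds (1 voxel, 1 degree); `"excluded"` traces
#' contain at least one excursion beyond a threshold, emulating repeated
#' swallowing-related movement.
#'
#' @param n_volumes Number of volumes (>= 1).
#' @param severity `"compliant"` or `"excluded"`.
#' @param seed Integer seed.
#' @param step_sd Random-walk step standard deviation.
#' @return 6 x n_volumes matrix, rows `trans_x/y/z` then `rot_x/y/z`.
#' @export
simulate_motion <- function(n_volumes, severity = c("compliant", "excluded"),
                            seed = 1, step_sd = 0.02) {
  assert_that(n_volumes >= 1, "n_volumes must be >= 1")
  severity <- match.arg(severity)
  with_rng(seed, {
    bound <- if (severity == "compliant") 0.6 else 0.9
    m <- t(sapply(seq_len(6), function(i) {
      walk <- cumsum(stats::rnorm(n_volumes, sd = step_sd))
      # reflect into [-bound, bound]
      w <- walk %% (4 * bound)
      w <- ifelse(w > 2 * bound, w - 4 * bound, w)
      ifelse(abs(w) > bound, sign(w) * (2 * bound - abs(w)), w)
    }))
    if (severity == "excluded") {
      # plant an excursion crossing the threshold on one translation and
      # one rotation trace (strictly beyond 1.0)
      at <- sample.int(n_volumes - 10L, 1L) + 5L
      span <- at:min(n_volumes, at + 8L)
      m[1L, span] <- m[1L, span] + 1.5
      m[4L, span] <- m[4L, span] - 1.3
    }
    rownames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
}

#' Simulate one subject's BOLD recording
#'
#' Forward model on the subject's own anatomy: the planted amplitude at a
#' subject vertex with ap coordinate `x` is the template layout evaluated
#' at the warped coordinate `warp(x)`. Taste responses are boxcars over
#' the delivery + tasting phases convolved with the canonical HRF; cue,
#' swallow and rinse events contribute nuisance responses at a fixed
#' fraction of the mean taste amplitude; a slow cosine drift and AR(1)
#' Gaussian noise are added per vertex.
#'
#' @param layout A `taste_layout` on the template patch.
#' @param patch The template `cortical_patch` (topology shared by subjects).
#' @param schedule A `stim_schedule`.
#' @param hrf An `hrf_kernel`.
#' @param warp The subject's ground-truth `subject_warp` (identity for a
#'   subject with template anatomy).
#' @param noise List with `sigma` (sd of the AR(1) innovations' stationary
#'   distribution), `ar1_rho` in (-1, 1) and `drift_amp`.
#' @param nuisance_frac Amplitude of cue/swallow/rinse responses as a
#'   fraction of the mean planted taste amplitude over the mask.
#' @param motion_severity Passed to [simulate_motion()].
#' @param subject_id Identifier stored with the recording.
#' @param seed Integer seed; the recording is a pure function of it.
#' @return A `subject_recording`: `bold` (n_vertices x n_volumes),
#'   `motion` (6 x n_volumes), `warp`, `subject_id`, `seed`,
#'   `true_amplitude` (the planted per-vertex x taste amplitudes on the
#'   subject's anatomy), `curvature` (subject's curvature profile),
#'   `patch` reference.
#' @export
simulate_subject <- function(layout, patch, schedule, hrf = canonical_hrf(),
                             warp = identity_warp(),
                             noise = list(sigma = 1, ar1_rho = 0.3,
                                          drift_amp = 0.5),
                             nuisance_frac = 0.5,
                             motion_severity = "compliant",
                             subject_id = "sub-01", seed = 1) {
  assert_that(noise$sigma >= 0, "noise sigma must be >= 0")
  assert_that(noise$ar1_rho > -1 && noise$ar1_rho < 1,
              "ar1_rho must lie in (-1, 1)")
  n_vert <- nrow(patch$vertices)
  assert_that(nrow(layout$amplitude) == n_vert,
              "layout and patch vertex counts differ")
  n <- schedule$n_volumes
  times <- (seq_len(n) - 1) * schedule$tr
  total <- schedule$total_duration
  timing <- schedule$timing
  taste_dur <- timing$delivery + timing$tasting

  # planted amplitude on the subject's anatomy (template layout read at
  # warped coordinates), masked like the template
  ap_warped <- warp_apply(warp, patch$ap_coord)
  amp <- layout_amplitude(layout, ap_warped)
  amp[!patch$mask, ] <- 0

  # task regressors identical in form to the analysis design
  Xt <- sapply(taste_labels(), function(tst) {
    ev <- schedule_events(schedule, tst)
    convolve_events(ev$onset, rep(taste_dur, nrow(ev)),
                    hrf$values, hrf$dt, total, times)
  })
  signal <- amp %*% t(Xt)

  nuis_amp <- nuisance_frac * mean(amp[patch$mask, ])
  nuis <- numeric(n)
  for (nm in c("cue", "swallow")) {
    ev <- schedule_events(schedule, nm)
    nuis <- nuis + convolve_events(ev$onset, ev$duration,
                                   hrf$values, hrf$dt, total, times)
  }
  ev <- schedule_events(schedule, "water")
  nuis <- nuis + convolve_events(ev$onset, rep(taste_dur, nrow(ev)),
                                 hrf$values, hrf$dt, total, times)
  signal <- signal + outer(rep(nuis_amp, n_vert), rep(1, n)) * rep(nuis, each = n_vert)

  with_rng(seed, {
    if (noise$drift_amp > 0) {
      # slow cosines below the high-pass band edge (periods >= 180 s)
      ks <- 1:8
      coef <- matrix(stats::rnorm(n_vert * length(ks), sd = noise$drift_amp / sqrt(length(ks))),
                     n_vert, length(ks))
      basis <- t(sapply(ks, function(k) cos(pi * k * (times + schedule$tr / 2) / total)))
      signal <- signal + coef %*% basis
    }
    if (noise$sigma > 0) {
      innov_sd <- noise$sigma * sqrt(1 - noise$ar1_rho^2)
      eps <- matrix(stats::rnorm(n_vert * n, sd = innov_sd), n_vert, n)
      if (noise$ar1_rho != 0) {
        # recursive filter; start-up transient decays within a few lags
        eps <- t(apply(eps, 1, function(e)
          stats::filter(e, noise$ar1_rho, method = "recursive")))
      }
      signal <- signal + eps
    }
    motion <- simulate_motion(n, motion_severity,
                              seed = stats::runif(1, 1, 2^30))
    out <- list(bold = signal, motion = motion, warp = warp,
                subject_id = subject_id, seed = seed,
                true_amplitude = amp,
                curvature = subject_curvature(patch, warp))
    class(out) <- "subject_recording"
    out
  })
}

# Subject's curvature field: template curvature profile read at warped
# coordinates (the anatomical feature that sits at template coordinate u
# appears at subject coordinate x with warp(x) = u).
subject_curvature <- function(patch, warp) {
  ap_w <- warp_apply(warp, patch$ap_coord)
  # template curvature is a function of ap only; interpolate the profile
  o <- order(patch$ap_coord)
  stats::approx(patch$ap_coord[o], patch$curvature[o], xout = ap_w,
                rule = 2, ties = mean)$y
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s: %d vertices x %d volumes (seed %s)\n",
              x$subject_id, nrow(x$bold), ncol(x$bold), format(x$seed)))
  invisible(x)
}
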