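#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking around
#' 5-6 s and a later undershoot, scaled to unit peak, together with its
#' temporal derivative (first finite difference). This is the standard
#' "canonical" HRF parameterization used in task-fMRI GLMs.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param peak_delay,undershoot_delay Gamma shape-times-scale delays (s).
#' @param peak_disp,undershoot_disp Dispersion (gamma scale, s).
#' @param ratio Undershoot amplitude relative to the peak.
#' @param length_s Kernel support in seconds.
#' @return An `hrf_kernel`: `dt`, `values`, `derivative`, `params`.
#' @export
canonical_hrf <- function(dt = 0.1, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          ratio = 1 / 6, length_s = 32) {
  assert_that(dt > 0, "dt must be positive")
  assert_that(peak_delay > 0 && undershoot_delay > 0 &&
                peak_disp > 0 && undershoot_disp > 0,
              "HRF delay/dispersion parameters must be positive")
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                          scale = undershoot_disp)
  h <- h / max(h)
  dh <- c(diff(h), 0) / dt
  out <- list(dt = dt, values = h, derivative = dh,
              params = list(peak_delay = peak_delay,
                            undershoot_delay = undershoot_delay,
                            peak_disp = peak_disp,
                            undershoot_disp = undershoot_disp,
                            ratio = ratio, length_s = length_s))
  class(out) <- "hrf_kernel"
  out
}

# Convolve a boxcar (defined by event onsets/durations on a fine time grid)
# with a kernel sampled at the same dt, then sample at volume times.
convolve_events <- function(onsets, durations, kernel_values, dt,
                            total_s, sample_times) {
  n_fine <- ceiling(total_s / dt) + length(kernel_values)
  box <- numeric(n_fine)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1L
    i1 <- max(i0, ceiling((onsets[k] + durations[k]) / dt))
    box[i0:min(i1, n_fine)] <- 1
  }
  conv <- stats::convolve(box, rev(kernel_values), type = "open") * dt
  conv <- conv[seq_len(n_fine)]
  idx <- pmin(n_fine, floor(sample_times / dt) + 1L)
  conv[idx]
}
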