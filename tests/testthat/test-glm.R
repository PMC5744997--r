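noiseless_recording <- function(p, l, s, seed = 5) {
  simulate_subject(l, p, s, noise = list(sigma = 0, ar1_rho = 0,
                                         drift_amp = 0), seed = seed)
}

test_that("the GLM recovers planted amplitudes exactly without noise", {
  p <- make_template_patch(120, seed = 2)
  l <- plant_layout(p)
  s <- build_schedule()
  r <- noiseless_recording(p, l, s)
  d <- build_design_matrix(s, motion = r$motion)
  bm <- fit_glm(r, d)
  expect_lt(max(abs(bm$beta - r$true_amplitude)), 1e-8)

  # OLS residuals orthogonal to every design column
  coefs <- qr.coef(qr(d$matrix), t(r$bold))
  res <- t(r$bold) - d$matrix %*% coefs
  expect_lt(max(abs(crossprod(d$matrix, res))) / max(abs(r$bold)), 1e-6)
})

test_that("a constant signal yields zero taste betas", {
  p <- make_template_patch(60, seed = 2)
  s <- build_schedule(sequences = default_sequences()[1])
  r <- list(bold = matrix(3.7, nrow(p$vertices), s$n_volumes),
            subject_id = "flat")
  d <- build_design_matrix(s)
  bm <- fit_glm(r, d)
  expect_lt(max(abs(bm$beta)), 1e-10)
})

test_that("reported standard errors match the empirical estimation error", {
  p <- make_template_patch(200, seed = 2)
  l <- plant_layout(p)
  s <- build_schedule()
  r <- simulate_subject(l, p, s, noise = list(sigma = 0.5, ar1_rho = 0,
                                              drift_amp = 0), seed = 11)
  d <- build_design_matrix(s, motion = r$motion)
  bm <- fit_glm(r, d)
  err_sd <- stats::sd(bm$beta - r$true_amplitude)  # 1200 iid errors
  expect_lt(abs(err_sd / mean(bm$se) - 1), 0.2)
})

test_that("temporal derivatives absorb small onset shifts", {
  p <- make_template_patch(60, seed = 2)
  l <- plant_layout(p)
  s <- build_schedule()
  d_with <- build_design_matrix(s, derivatives = TRUE)
  d_without <- build_design_matrix(s, derivatives = FALSE)
  errs <- sapply(c(-1, 1), function(shift) {
    s_shift <- s
    s_shift$events$onset <- pmax(0, s_shift$events$onset + shift)
    r <- noiseless_recording(p, l, s_shift)
    Y <- t(r$bold)
    rss <- function(d) sum((Y - d$matrix %*% qr.coef(qr(d$matrix), Y))^2)
    # derivative columns always absorb shift-induced misfit (nested models)
    expect_lte(rss(d_with), rss(d_without) + 1e-8)
    c(with = mean(abs(fit_glm(r, d_with)$beta - r$true_amplitude)),
      without = mean(abs(fit_glm(r, d_without)$beta - r$true_amplitude)))
  })
  # averaged over +/-1 s latency shifts the derivative model estimates the
  # planted amplitudes at least as accurately
  expect_lte(mean(errs["with", ]), mean(errs["without", ]))
})

test_that("mismatched volume counts and all-NaN series are rejected", {
  p <- make_template_patch(60, seed = 2)
  s <- build_schedule(sequences = default_sequences()[1])
  d <- build_design_matrix(s)
  expect_error(fit_glm(list(bold = matrix(0, 10, 5)), d), "volumes")
  bold <- matrix(rnorm(10 * s$n_volumes), 10)
  bold[3, ] <- NaN
  expect_error(fit_glm(list(bold = bold), d), "NaN")
})

test_that("surface smoothing is calibrated, identity at fwhm 0, and mean-preserving", {
  p <- make_template_patch(1600, seed = 1, length_mm = 99, width_mm = 15,
                           fold_amp_mm = 0)
  x <- rnorm(nrow(p$vertices))
  expect_identical(smooth_map(x, p, fwhm = 0), x)
  expect_lt(max(abs(smooth_map(rep(2.5, nrow(p$vertices)), p, 8) - 2.5)), 1e-9)

  # diffusion-variance calibration: impulse spread ~ fwhm / 2.3548
  imp <- numeric(nrow(p$vertices))
  ctr <- which.min(rowSums(sweep(p$vertices[, 1:2], 2, c(49.5, 7.5))^2))
  imp[ctr] <- 1
  sm <- smooth_map(imp, p, fwhm = 8)
  w <- sm / sum(sm)
  mu <- sum(w * p$vertices[, 1])
  sd_x <- sqrt(sum(w * (p$vertices[, 1] - mu)^2))
  expect_lt(abs(sd_x / (8 / 2.3548) - 1), 0.15)
  # mass preserved up to boundary effects
  expect_lt(abs(sum(sm) - 1), 0.05)
  expect_error(smooth_map(x, p, fwhm = -1), "fwhm")
})
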