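test_that("curvature profiles summarize the folding pattern", {
  p <- make_template_patch(600, seed = 1)
  # flat patch: all-zero profile
  flat <- curvature_profile(p$ap_coord, rep(0, nrow(p$vertices)), 24)
  expect_equal(flat$profile, rep(0, 24))

  # sinusoid with k periods crosses zero ~2k times
  prof <- patch_profile(p, 48)
  crossings <- sum(diff(sign(prof$profile)) != 0)
  expect_gte(crossings, 2 * 4 - 1)
  expect_lte(crossings, 2 * 4 + 1)

  # a warped subject's profile differs from the template's
  w <- random_warp(0.1, seed = 3)
  pw <- curvature_profile(p$ap_coord, tastemap:::subject_curvature(p, w), 48)
  expect_gt(max(abs(pw$profile - prof$profile)), 0.1)
  expect_error(curvature_profile(p$ap_coord, p$curvature, 3), "n_bins")
})

test_that("warps are validated, monotone, and invertible", {
  expect_error(make_warp(c(0, 0.5, 1), c(0, 0.6, 0.4)), "increasing")
  expect_error(make_warp(c(0, 0.5, 1), c(0.1, 0.5, 1)), "anchored")
  w <- random_warp(0.1, seed = 7)
  g <- seq(0, 1, length.out = 200)
  expect_true(all(diff(warp_apply(w, g)) > 0))
  winv <- warp_invert(w)
  expect_lt(max(abs(warp_apply(winv, warp_apply(w, g)) - g)), 1e-3)
})

test_that("identical subjects align with identity warps and zero residual", {
  p <- make_template_patch(400, seed = 1)
  prof <- patch_profile(p, 48)
  al <- moving_target_align(rep(list(prof), 4))
  expect_lt(tail(al$convergence, 1), 1e-12)
  for (w in al$warps)
    expect_lt(max(abs(w$knots_u - w$knots_x)), 1e-8)
})

test_that("planted warps are recovered and curvature variance shrinks", {
  p <- make_template_patch(600, seed = 1)
  true_warps <- lapply(1:6, function(s) random_warp(0.08, seed = s))
  profiles <- lapply(true_warps, function(w)
    curvature_profile(p$ap_coord, tastemap:::subject_curvature(p, w), 48))
  al <- moving_target_align(profiles)
  expect_lt(tail(al$convergence, 1), al$convergence[1])
  g <- seq(0.02, 0.98, length.out = 100)
  mae <- mean(sapply(seq_along(true_warps), function(s)
    mean(abs(warp_apply(al$warps[[s]], g) - warp_apply(true_warps[[s]], g)))))
  expect_lt(mae, 0.02)
  # warps remain order-preserving bijections of [0, 1]
  for (w in al$warps) {
    expect_true(all(diff(warp_apply(w, g)) > 0))
    expect_equal(warp_apply(w, c(0, 1)), c(0, 1), tolerance = 1e-8)
  }
})

test_that("map resampling interpolates through the warp", {
  # dense grid: linear-interpolation error of the warp-curved map scales
  # with (grid spacing)^2 times the warp's second derivative, which grows
  # steeply as the warp slope approaches zero — keep the displacement in
  # the well-conditioned anatomical range
  p <- make_template_patch(2400, seed = 1)
  x <- sin(2 * p$ap_coord) + 0.2 * p$lat_coord
  # identity warp: unchanged
  expect_equal(resample_map(x, identity_warp(), p), x, tolerance = 1e-9)
  # constants survive any warp
  w <- random_warp(0.08, seed = 2)
  expect_equal(resample_map(rep(1.3, length(x)), w, p),
               rep(1.3, length(x)), tolerance = 1e-12)
  # warp then inverse-warp round trip on a smooth map
  y <- resample_map(x, w, p)
  x_back <- resample_map(y, warp_invert(w), p)
  interior <- p$ap_coord > 0.1 & p$ap_coord < 0.9
  expect_lt(max(abs(x_back[interior] - x[interior])), 1e-3)
})

test_that("group averaging is the vertex-wise mean", {
  m <- matrix(rnorm(50 * 6), 50)
  expect_equal(group_average(list(m)), m)
  expect_equal(group_average(list(m, -m)), matrix(0, 50, 6))
  expect_equal(group_average(list(m, m + 2)), m + 1)
})

test_that("alignment improves inter-subject beta-map correspondence", {
  run <- default_run()
  res <- run$res
  patch <- run$cohort$patch
  m <- patch$mask
  n_sub <- length(res$betas)
  pair_cor <- function(maps) {
    cc <- c()
    for (i in 1:(n_sub - 1)) for (j in (i + 1):n_sub)
      cc <- c(cc, stats::cor(as.vector(maps[[i]][m, ]),
                             as.vector(maps[[j]][m, ])))
    mean(cc)
  }
  unaligned <- lapply(res$betas, `[[`, "beta")
  expect_gte(pair_cor(res$aligned_betas), pair_cor(unaligned))
})
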