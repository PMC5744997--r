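make_z <- function(zmat, mask = rep(TRUE, nrow(zmat))) {
  colnames(zmat) <- taste_labels()[seq_len(ncol(zmat))]
  structure(list(z = zmat, mask = mask), class = "zscore_maps")
}

test_that("z-scoring matches the direct standardization formula", {
  # constant map with a unit impulse on one vertex, 100-vertex mask
  n <- 100
  beta <- matrix(1, n, 6, dimnames = list(NULL, taste_labels()))
  beta[1, ] <- 2
  z <- zscore_maps(beta, rep(TRUE, n))
  v <- beta[, 1]
  expect_equal(unname(z$z[1, 1]), (2 - mean(v)) / stats::sd(v))
  expect_equal(unname(z$z[1, 1]), (1 - 1 / n) / stats::sd(v))

  # standardization identity over the mask
  set.seed(5)
  beta2 <- matrix(rnorm(n * 6), n)
  z2 <- zscore_maps(beta2, rep(TRUE, n))
  expect_lt(max(abs(colMeans(z2$z))), 1e-9)
  expect_lt(max(abs(apply(z2$z, 2, stats::sd) - 1)), 1e-9)

  # positive affine transforms leave z untouched
  z3 <- zscore_maps(3.7 * beta2 + 11, rep(TRUE, n))
  expect_equal(z2$z, z3$z, tolerance = 1e-12)

  expect_error(zscore_maps(matrix(1, n, 6), rep(TRUE, n)), "zero variance")
  expect_error(zscore_maps(beta2, c(TRUE, rep(FALSE, n - 1))), "mask")
})

test_that("ranking matches an exhaustive sort oracle", {
  set.seed(12)
  n <- 1000
  Z <- matrix(rnorm(n * 6), n, 6)
  pm <- rank_and_win(make_z(Z))
  for (v in sample(n, 200)) {
    ord <- order(Z[v, ], decreasing = TRUE)
    expect_equal(pm$winner[v], taste_labels()[ord[1]])
    expect_equal(unname(pm$ranks[v, ord]), 1:6)
  }
  # normalized preference anchors: rank 1 -> 1, rank 6 -> 0
  expect_true(all(pm$normalized_pref[cbind(1:n, max.col(Z))] == 1))
  worst <- apply(Z, 1, which.min)
  expect_true(all(pm$normalized_pref[cbind(1:n, worst)] == 0))
})

test_that("saturation encodes the winner margin as a percentage", {
  # top z exactly twice the runner-up: 100%
  pm <- rank_and_win(make_z(rbind(c(2, 1, 0.5, 0, -0.5, -1))))
  expect_equal(pm$saturation[1], 100)
  expect_equal(unname(pm$normalized_pref[1, "sweet"]), 1)

  # equal top pair: 0%; non-positive runner-up: reported at the cap
  expect_equal(rank_and_win(make_z(rbind(c(1, 1, 0, 0, 0, -1))))$saturation[1], 0)
  pm_deg <- rank_and_win(make_z(rbind(c(1, -0.2, -0.4, -0.6, -0.8, -1))))
  expect_equal(pm_deg$saturation[1], 200)
  pm_cap <- rank_and_win(make_z(rbind(c(5, 0.001, -1, -2, -3, -4))))
  expect_equal(pm_cap$saturation[1], 200)

  # deterministic canonical-order tie-break
  pm_tie <- rank_and_win(make_z(rbind(c(1, 1, 1, 1, 1, 1) * 0 + 2)))
  expect_equal(pm_tie$winner[1], "sweet")
})

test_that("excluding a taste remaps only its own territory", {
  Z <- rbind(
    c(0.2, 1.5, 0.1, 0.5, -0.1, 3.0),   # co2 wins, bitter clear runner-up
    c(0.1, 1.02, 0.2, 1.00, -0.5, 2.5), # co2 wins, near-tied runners-up
    c(2.0, 0.5, 0.1, 0.3, -0.2, 1.0)    # sweet wins outright
  )
  z <- make_z(Z)
  pm0 <- rank_and_win(z)
  expect_equal(pm0$winner, c("co2", "co2", "sweet"))

  pm <- exclude_taste_remap(z, "co2", clarity_min = 5)
  expect_equal(colnames(pm$ranks), setdiff(taste_labels(), "co2"))
  # former co2 vertex with a clear margin goes to its old rank-2 taste
  expect_equal(pm$winner[1], "bitter")
  # margin below clarity_min (2% here) becomes unassigned
  expect_equal(pm$winner[2], "unassigned")
  # vertices not owned by the excluded taste keep their winner
  expect_equal(pm$winner[3], "sweet")
  # preference renormalized over 5 tastes: best 1, worst 0
  expect_equal(max(pm$normalized_pref[3, ]), 1)
  expect_equal(min(pm$normalized_pref[3, ]), 0)

  expect_error(exclude_taste_remap(z, "fat"), "unknown taste")
  expect_error(exclude_taste_remap(z, "co2", clarity_min = -1), "clarity_min")
})

test_that("exclusion never changes the winner where the excluded taste lost", {
  set.seed(31)
  Z <- matrix(rnorm(500 * 6), 500)
  z <- make_z(Z)
  pm0 <- rank_and_win(z)
  pm1 <- exclude_taste_remap(z, "umami", clarity_min = 0)
  keep <- pm0$winner != "umami"
  expect_equal(pm1$winner[keep], pm0$winner[keep])
})

test_that("cluster preference profiles partition the assigned vertices", {
  p <- small_patch()
  # single-winner map: one cluster with own-taste preference 1
  Z <- matrix(0, nrow(p$vertices), 6)
  Z[, 2] <- 2
  Z <- Z + matrix(rnorm(length(Z), sd = 1e-3), nrow(Z))  # break exact ties
  Z[, 2] <- Z[, 2] + 10
  pm <- rank_and_win(make_z(Z, p$mask))
  cp <- cluster_preferences(pm, p)
  expect_equal(nrow(cp$clusters), 1)
  expect_equal(cp$clusters$winner, "bitter")
  expect_equal(unname(cp$mean_pref[1, "bitter"]), 1)
  # membership covers exactly the assigned masked vertices
  expect_equal(which(cp$membership > 0), which(p$mask))
})

test_that("similarity statistics behave at their fixed points", {
  p <- small_patch()
  m <- p$mask
  set.seed(14)
  G <- matrix(rnorm(nrow(p$vertices) * 6), ncol = 6,
              dimnames = list(NULL, taste_labels()))
  gz <- zscore_maps(G, m)
  gpm <- rank_and_win(gz)
  sim <- similarity_analysis(list(G), list(gpm), G, gpm, m,
                             n_perm = 200, seed = 3)
  expect_equal(sim$pearson$r, rep(1, 6))
  expect_equal(sim$spearman$rho, 1)
  expect_true(all(sim$pearson$p <= 0.01))

  # a vertex-permuted subject decorrelates
  Gp <- G
  Gp[m, ] <- G[sample(which(m)), ]
  sim2 <- similarity_analysis(list(Gp), list(gpm), G, gpm, m,
                              n_perm = 200, seed = 4)
  expect_lt(max(abs(sim2$pearson$r)), 0.2)

  # constant maps are reported missing with a warning
  Gc <- G; Gc[, 1] <- 1
  expect_warning(sim3 <- similarity_analysis(list(Gc), list(gpm), G, gpm, m,
                                             n_perm = 100, seed = 5),
                 "constant map")
  expect_true(is.na(sim3$pearson$r[sim3$pearson$taste == "sweet"]))
})

test_that("the full prevalence output is invariant to per-taste affine rescaling", {
  p <- small_patch()
  set.seed(18)
  B <- matrix(rnorm(nrow(p$vertices) * 6), ncol = 6,
              dimnames = list(NULL, taste_labels()))
  B2 <- sweep(sweep(B, 2, c(2, 0.5, 3, 1.5, 4, 2.2), `*`),
              2, c(-1, 2, 0, 5, -3, 1), `+`)
  pm1 <- rank_and_win(zscore_maps(B, p$mask))
  pm2 <- rank_and_win(zscore_maps(B2, p$mask))
  expect_equal(pm1$winner, pm2$winner)
  expect_equal(pm1$ranks, pm2$ranks)
  expect_equal(pm1$saturation, pm2$saturation, tolerance = 1e-9)
})
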