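fake_rec <- function(motion, id = "sub-x") list(motion = motion, subject_id = id)

test_that("the exclusion rule is a strict 'more than' threshold", {
  zeros <- matrix(0, 6, 50)
  ok <- fake_rec(zeros, "ok")  # companion so the cohort never empties
  expect_equal(motion_exclusion(list(ok))$decision, "keep")

  at_thresh <- zeros; at_thresh[1, 10] <- 1.0        # exactly one voxel
  expect_equal(motion_exclusion(list(fake_rec(at_thresh)))$decision, "keep")

  over_t <- zeros; over_t[2, 10] <- 1.0001
  expect_equal(motion_exclusion(list(ok, fake_rec(over_t)))$decision,
               c("keep", "exclude"))
  over_r <- zeros; over_r[5, 10] <- -1.2             # rotation, sign ignored
  expect_equal(motion_exclusion(list(ok, fake_rec(over_r)))$decision,
               c("keep", "exclude"))
})

test_that("QC equals a brute-force maximum over random traces", {
  set.seed(42)
  ok <- fake_rec(matrix(0, 6, 80), "ok")
  for (i in 1:20) {
    m <- matrix(rnorm(6 * 80, sd = 0.6), 6)
    rep_df <- motion_exclusion(list(ok, fake_rec(m)), trans_thresh = 0.9,
                               rot_thresh = 1.1)[2, ]
    want <- if (max(abs(m[1:3, ])) > 0.9 || max(abs(m[4:6, ])) > 1.1)
      "exclude" else "keep"
    expect_equal(rep_df$decision, want)
    expect_equal(rep_df$max_translation, max(abs(m[1:3, ])))
    expect_equal(rep_df$max_rotation, max(abs(m[4:6, ])))
  }
})

test_that("a cohort with two planted violators retains eight subjects", {
  recs <- lapply(1:10, function(s)
    fake_rec(simulate_motion(720, if (s > 8) "excluded" else "compliant",
                             seed = s), sprintf("sub-%02d", s)))
  rep_df <- motion_exclusion(recs)
  expect_equal(sum(rep_df$decision == "keep"), 8)
  expect_equal(attr(rep_df, "kept"), 1:8)
  expect_error(motion_exclusion(recs[9:10]), "all subjects excluded")
})

test_that("group t statistics behave like a one-sample t test", {
  # degenerate zero-variance vertices
  m <- matrix(rep(c(1, 0), each = 4), nrow = 4, ncol = 2)
  expect_warning(tmap <- group_ttest(m), "zero across-subject variance")
  expect_equal(tmap, c(Inf, 0))

  # null calibration: rejection rate at the two-sided 5% critical value
  set.seed(8)
  B <- matrix(rnorm(8 * 1000), 8)
  t_null <- group_ttest(B)
  frac <- mean(abs(t_null) > stats::qt(0.975, 7))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)

  # scaling: mu/sigma = 2 with n = 8 gives mean t ~ 2 * sqrt(8)
  set.seed(9)
  Bs <- matrix(rnorm(8 * 500, mean = 2), 8)
  expect_lt(abs(mean(group_ttest(Bs)) / (2 * sqrt(8)) - 1), 0.15)
})

test_that("cluster-level permutation p values respect their bounds and ordering", {
  p <- small_patch()
  set.seed(21)
  # all-positive maps: the observed pattern is among the sign flips, so
  # corrected p is at least 1 / (1 + n_perm)
  B <- matrix(abs(rnorm(8 * nrow(p$vertices))) + 2, 8)
  tmap <- group_ttest(B, mask = p$mask)
  ct <- cluster_fwe(tmap, p, B, n_perm = 120, seed = 1)
  all_ct <- attr(ct, "all_clusters")
  expect_true(all(all_ct$p_fwe >= 1 / 121))
  expect_true(all(all_ct$p_fwe <= 1))
  # p monotone non-increasing in observed cluster size
  o <- order(all_ct$size)
  expect_true(all(diff(all_ct$p_fwe[o]) <= 0 | diff(all_ct$size[o]) == 0))
})

test_that("a strong planted cluster is detected and pure noise yields none", {
  p <- small_patch()
  set.seed(33)
  B <- matrix(rnorm(8 * nrow(p$vertices)), 8)
  verts <- which(p$mask)[1:30]
  B[, verts] <- B[, verts] + 5
  tmap <- group_ttest(B, mask = p$mask)
  ct <- cluster_fwe(tmap, p, B, n_perm = 200, seed = 2)
  expect_gt(nrow(ct), 0)
  expect_lte(min(ct$p_fwe), 0.05)
  expect_true(any(ct$size >= 25))

  # sub-threshold t map: empty table, not an error
  Bn <- matrix(rnorm(8 * nrow(p$vertices), sd = 1e-3), 8)
  tn <- group_ttest(Bn, mask = p$mask)
  tn[!is.na(tn)] <- 0
  ct0 <- cluster_fwe(tn, p, Bn, n_perm = 120, seed = 3)
  expect_equal(nrow(ct0), 0)
})
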