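test_that("template patches are deterministic, connected and near-flat in mean curvature", {
  p1 <- make_template_patch(500, seed = 1)
  p2 <- make_template_patch(500, seed = 1)
  expect_identical(p1, p2)

  # connectivity established by breadth-first search over the face graph
  adj <- patch_adjacency(p1)
  lab <- tastemap:::mesh_components(adj, rep(TRUE, nrow(p1$vertices)))
  expect_equal(max(lab), 1L)

  # a whole number of sinusoid periods integrates to ~0
  expect_lt(abs(mean(p1$curvature)), 0.02)
  expect_true(any(p1$mask))
  expect_true(all(p1$faces >= 1 & p1$faces <= nrow(p1$vertices)))
  # ap_coord monotone along the strip's long axis
  expect_true(all(diff(p1$ap_coord[seq(1, nrow(p1$vertices), by = p1$nv)]) > 0))
})

test_that("tiny patches are rejected", {
  expect_error(make_template_patch(10), "n_vertices")
})

test_that("planted layouts put each taste's argmax at its own center, in order", {
  p <- small_patch()
  l0 <- plant_layout(p, overlap = 0)
  # at the vertex nearest each center the planted taste wins
  for (tst in taste_labels()) {
    ctr <- l0$cluster_centers[tst]
    v <- which(p$mask)[which.min(abs(p$ap_coord[p$mask] - ctr))]
    expect_equal(taste_labels()[which.max(l0$amplitude[v, ])], tst)
  }
  # argmax sequence along ap follows the planted posterior->anterior order
  l <- plant_layout(p)
  masked <- which(p$mask)
  ord <- masked[order(p$ap_coord[masked])]
  winners <- taste_labels()[apply(l$amplitude[ord, ], 1, which.max)]
  expect_equal(unique(winners), planted_order())

  # cross-talk keeps every amplitude strictly positive inside the mask
  expect_true(all(l$amplitude[p$mask, ] > 0))
  expect_true(all(l$amplitude[!p$mask, ] == 0))
})

test_that("cross-talk mixing never changes the winning taste", {
  p <- small_patch()
  l0 <- plant_layout(p, overlap = 0)
  l5 <- plant_layout(p, overlap = 0.5)
  m <- p$mask
  expect_equal(apply(l0$amplitude[m, ], 1, which.max),
               apply(l5$amplitude[m, ], 1, which.max))
})

test_that("layout parameter validation", {
  p <- small_patch()
  expect_error(plant_layout(p, width = 0), "width")
  expect_error(plant_layout(p, overlap = 1), "overlap")
  expect_error(plant_layout(p, ordering = taste_labels()[1:5]), "permute")
})
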