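#' Z-score beta maps over the insular mask
#'
#' For each taste, every masked vertex's beta is expressed as the number of
#' standard deviations from the mean beta over the entire mask:
#' `z(v, t) = (beta(v, t) - mean_mask(beta(., t))) / sd_mask(beta(., t))`.
#' Vertices outside the mask carry `NA`. This standardization makes the
#' downstream ranking invariant to positive affine rescaling of each
#' taste's map (overall activity differences between tastants drop out).
#'
#' @param betas A `beta_maps` object or an n_vertices x 6 matrix.
#' @param mask Logical vertex mask with >= 2 `TRUE` entries.
#' @return A `zscore_maps` object: `z` (n_vertices x 6, NA off-mask),
#'   `mask`.
#' @export
zscore_maps <- function(betas, mask) {
  B <- if (inherits(betas, "beta_maps")) betas$beta else as.matrix(betas)
  assert_that(sum(mask) >= 2, "mask must contain >= 2 vertices")
  assert_that(nrow(B) == length(mask), "betas and mask sizes differ")
  Z <- matrix(NA_real_, nrow(B), ncol(B),
              dimnames = list(NULL, colnames(B) %||% taste_labels()))
  for (j in seq_len(ncol(B))) {
    v <- B[mask, j]
    s <- stats::sd(v)
    assert_that(s > 0, "zero variance over the mask for taste '%s'",
                colnames(Z)[j])
    Z[mask, j] <- (B[mask, j] - mean(v)) / s
  }
  out <- list(z = Z, mask = mask)
  class(out) <- "zscore_maps"
  out
}

#' Rank tastes per vertex and build the winner (prevalence) map
#'
#' At every masked vertex the six taste z-scores are sorted in descending
#' order. The winner ("best stimulus") is the rank-1 taste; ties are broken
#' by the canonical taste order (deterministic). Saturation encodes the
#' winner's margin over the runner-up as a percentage,
#' `100 * (z1 - z2) / z2`, so 100% means the first-ranked taste is twice
#' the second-ranked one; when the runner-up z is not positive the ratio is
#' undefined and the saturation is reported at `saturation_cap` (all values
#' are capped there). Ranks are normalized to a 0-1 preference score,
#' `(R - rank) / (R - 1)`: 1 for the best taste, 0 for the worst.
#'
#' @param z A `zscore_maps` object (or a list with `z` and `mask`).
#' @param saturation_cap Maximum reported saturation percentage.
#' @return A `prevalence_map`: `winner` (character, NA off-mask),
#'   `saturation` (percent), `ranks` (n x R matrix; entry = rank of that
#'   taste at that vertex, 1 = best), `normalized_pref` (n x R in \[0,1\]),
#'   `mask`, `tastes`.
#' @export
rank_and_win <- function(z, saturation_cap = 200) {
  Z <- z$z
  mask <- z$mask
  tastes <- colnames(Z)
  R <- length(tastes)
  assert_that(R >= 2, "ranking needs at least 2 tastes")
  n <- nrow(Z)

  ranks <- matrix(NA_real_, n, R, dimnames = list(NULL, tastes))
  winner <- rep(NA_character_, n)
  saturation <- rep(NA_real_, n)

  # canonical order breaks ties deterministically: earlier column wins
  for (v in which(mask)) {
    zv <- Z[v, ]
    ord <- order(-zv, seq_len(R))     # descending z, ties by column order
    ranks[v, ord] <- seq_len(R)
    winner[v] <- tastes[ord[1]]
    z1 <- zv[ord[1]]; z2 <- zv[ord[2]]
    saturation[v] <- if (z2 > 0) min(100 * (z1 - z2) / z2, saturation_cap)
      else saturation_cap
  }
  pref <- (R - ranks) / (R - 1)

  out <- list(winner = winner, saturation = saturation, ranks = ranks,
              normalized_pref = pref, mask = mask, tastes = tastes)
  class(out) <- "prevalence_map"
  out
}

#' @export
print.prevalence_map <- function(x, ...) {
  tab <- table(x$winner[x$mask])
  cat(sprintf("<prevalence_map> %d assigned vertices over %d tastes\n",
              sum(!is.na(x$winner[x$mask])), length(x$tastes)))
  print(tab)
  invisible(x)
}

#' Re-map prevalence after excluding one taste
#'
#' Drops one taste and recomputes the ranking over the remaining R - 1
#' tastes (preference normalization uses the reduced R). Vertices whose new
#' winner margin (saturation) falls below `clarity_min` are labeled
#' `"unassigned"`: none of the remaining tastes exhibits a clear prevalence
#' there.
#'
#' @param z A `zscore_maps` object with all six tastes.
#' @param excluded The taste label to remove.
#' @param clarity_min Minimum saturation (percent) for a vertex to stay
#'   assigned; default 5.
#' @param saturation_cap Passed to [rank_and_win()].
#' @return A `prevalence_map` over the remaining tastes, with
#'   `"unassigned"` winners where clarity fails and `excluded` recorded.
#' @export
exclude_taste_remap <- function(z, excluded, clarity_min = 5,
                                saturation_cap = 200) {
  assert_that(clarity_min >= 0, "clarity_min must be >= 0")
  tastes <- colnames(z$z)
  assert_that(excluded %in% tastes, "unknown taste '%s'", excluded)
  zred <- list(z = z$z[, setdiff(tastes, excluded), drop = FALSE],
               mask = z$mask)
  class(zred) <- "zscore_maps"
  pm <- rank_and_win(zred, saturation_cap = saturation_cap)
  unclear <- !is.na(pm$saturation) & pm$saturation < clarity_min
  pm$winner[unclear] <- "unassigned"
  pm$excluded <- excluded
  pm$clarity_min <- clarity_min
  pm
}

#' Cluster-wise preference profiles
#'
#' Clusters are connected components (mesh adjacency) of vertices sharing
#' the same winning taste; components smaller than `min_size` are merged
#' into the neighbouring cluster with the most shared boundary edges (with
#' a message). For each cluster the normalized preference scores of all
#' tastes are averaged over member vertices.
#'
#' @param pmap A `prevalence_map`.
#' @param patch The `cortical_patch` the map lives on.
#' @param min_size Minimum cluster size before merging; default 1 (keep
#'   all).
#' @return A `cluster_preference` list: `clusters` (data frame with
#'   `cluster`, `winner`, `size`, `centroid_ap`), `mean_pref` (cluster x
#'   taste matrix), `membership` (per-vertex cluster id, 0 = none).
#' @export
cluster_preferences <- function(pmap, patch, min_size = 1) {
  adj <- patch_adjacency(patch)
  assigned <- which(pmap$mask & !is.na(pmap$winner) &
                      pmap$winner != "unassigned")
  assert_that(length(assigned) > 0, "prevalence map has no assigned vertices")

  membership <- integer(length(pmap$winner))
  next_id <- 0L
  for (tst in unique(pmap$winner[assigned])) {
    verts <- assigned[pmap$winner[assigned] == tst]
    lab <- mesh_components(adj, verts)
    for (l in unique(lab[verts])) {
      next_id <- next_id + 1L
      membership[verts[lab[verts] == l]] <- next_id
    }
  }

  if (min_size > 1) membership <- merge_small_clusters(membership, adj, min_size)

  ids <- sort(unique(membership[membership > 0L]))
  clusters <- do.call(rbind, lapply(seq_along(ids), function(k) {
    vs <- which(membership == ids[k])
    data.frame(cluster = k,
               winner = names(which.max(table(pmap$winner[vs]))),
               size = length(vs),
               centroid_ap = mean(patch$ap_coord[vs]),
               stringsAsFactors = FALSE)
  }))
  mean_pref <- t(vapply(seq_along(ids), function(k) {
    vs <- which(membership == ids[k])
    colMeans(pmap$normalized_pref[vs, , drop = FALSE])
  }, numeric(length(pmap$tastes))))
  colnames(mean_pref) <- pmap$tastes
  membership[membership > 0L] <- match(membership[membership > 0L], ids)

  out <- list(clusters = clusters, mean_pref = mean_pref,
              membership = membership)
  class(out) <- "cluster_preference"
  out
}

# Merge components below min_size into the neighbouring cluster sharing the
# most boundary edges; isolated small islands keep their label if no
# neighbour exists.
merge_small_clusters <- function(membership, adj, min_size) {
  repeat {
    sizes <- table(membership[membership > 0L])
    small <- as.integer(names(sizes)[sizes < min_size])
    if (!length(small)) break
    changed <- FALSE
    for (cid in small) {
      vs <- which(membership == cid)
      nb_ids <- unlist(lapply(vs, function(v) {
        m <- membership[adj[[v]]]
        m[m > 0L & m != cid]
      }))
      if (!length(nb_ids)) next
      target <- as.integer(names(which.max(table(nb_ids))))
      membership[vs] <- target
      changed <- TRUE
      message(sprintf("cluster_preferences: merged cluster %d (%d vertices) into %d",
                      cid, length(vs), target))
    }
    if (!changed) break
  }
  membership
}

#' Individual-to-group map similarity
#'
#' For every subject: Pearson correlation (per taste) between the
#' subject's aligned beta map and the group beta map over the mask, and
#' Spearman correlation between the subject's and the group's preference
#' maps — computed on the concatenated per-vertex normalized-preference
#' vectors of all tastes, since the information in a preference map is
#' carried by the rank of each taste. P values come from a vertex-
#' permutation null: the subject's masked vertex order is shuffled
#' `n_perm` times (one-sided, positive association).
#'
#' @param subject_betas List of n_vertices x 6 beta matrices (aligned).
#' @param subject_pmaps List of `prevalence_map`s, one per subject.
#' @param group_betas Group-average n_vertices x 6 beta matrix.
#' @param group_pmap Group `prevalence_map`.
#' @param mask Logical vertex mask (common template mask).
#' @param n_perm Number of vertex permutations.
#' @param seed Integer seed.
#' @return A `similarity_report`: `pearson` (data frame subject x taste
#'   with `r`, `p`), `spearman` (data frame per subject with `rho`, `p`).
#' @export
similarity_analysis <- function(subject_betas, subject_pmaps, group_betas,
                                group_pmap, mask, n_perm = 1000, seed = 1) {
  n_sub <- length(subject_betas)
  midx <- which(mask)
  tastes <- taste_labels()

  with_rng(seed, {
    perms <- replicate(n_perm, sample(length(midx)), simplify = FALSE)

    pearson <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
      do.call(rbind, lapply(seq_along(tastes), function(j) {
        x <- subject_betas[[s]][midx, j]
        y <- group_betas[midx, j]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          warning(sprintf("constant map (subject %d, %s); correlation undefined",
                          s, tastes[j]))
          return(data.frame(subject = s, taste = tastes[j],
                            r = NA_real_, p = NA_real_))
        }
        r <- stats::cor(x, y)
        null_r <- vapply(perms, function(pp) stats::cor(x[pp], y), numeric(1))
        data.frame(subject = s, taste = tastes[j], r = r,
                   p = (1 + sum(null_r >= r)) / (1 + n_perm),
                   stringsAsFactors = FALSE)
      }))
    }))

    spearman <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
      xs <- as.vector(subject_pmaps[[s]]$normalized_pref[midx, ])
      ys <- as.vector(group_pmap$normalized_pref[midx, ])
      rho <- stats::cor(xs, ys, method = "spearman")
      null_rho <- vapply(perms, function(pp) {
        xp <- as.vector(subject_pmaps[[s]]$normalized_pref[midx, ][pp, ])
        stats::cor(xp, ys, method = "spearman")
      }, numeric(1))
      data.frame(subject = s, rho = rho,
                 p = (1 + sum(null_rho >= rho)) / (1 + n_perm))
    }))
  })

  out <- list(pearson = pearson, spearman = spearman, n_perm = n_perm)
  class(out) <- "similarity_report"
  out
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> %d subjects; median Pearson r %.3f, median Spearman rho %.3f\n",
              max(x$pearson$subject), stats::median(x$pearson$r, na.rm = TRUE),
              stats::median(x$spearman$rho)))
  invisible(x)
}
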