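#' One-sample group t map (random-effects analysis)
#'
#' Treats subjects as random draws: at every masked vertex the across-
#' subject mean of the per-subject contrast estimates is tested against
#' zero with a one-sample t statistic (df = n_subjects - 1). Vertices with
#' zero across-subject variance get t = +/-Inf (logged via a warning).
#'
#' @param betas n_subjects x n_vertices matrix of aligned per-subject
#'   contrast maps for one taste.
#' @param mask Optional logical vector; t is NA outside it.
#' @return Numeric per-vertex t map.
#' @export
group_ttest <- function(betas, mask = NULL) {
  assert_that(nrow(betas) >= 2, "group t test needs >= 2 subjects")
  n <- nrow(betas)
  m <- colMeans(betas)
  s <- sqrt(colSums(sweep(betas, 2, m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  zero_var <- s == 0 & m != 0
  if (any(zero_var, na.rm = TRUE)) {
    warning(sprintf("%d vertex(es) with zero across-subject variance; t set to +/-Inf",
                    sum(zero_var, na.rm = TRUE)))
    t[zero_var] <- sign(m[zero_var]) * Inf
  }
  t[s == 0 & m == 0] <- 0
  if (!is.null(mask)) t[!mask] <- NA_real_
  t
}

#' Cluster-level FWE-corrected inference by sign-flip permutation
#'
#' Clusters are connected components (mesh edge adjacency) of masked
#' vertices whose group t statistic exceeds the one-sided cluster-forming
#' threshold `qt(1 - cf_p, df)`. The null distribution of the maximum
#' cluster size is built by randomly sign-flipping whole subject maps and
#' recomputing the t map; the corrected p of an observed cluster of size s
#' is `(1 + #\{null max >= s\}) / (1 + n_perm)`. Clusters with corrected
#' p <= alpha are reported.
#'
#' @param tmap Observed per-vertex t map (as from [group_ttest()]).
#' @param patch A `cortical_patch` supplying adjacency, coordinates and the
#'   default mask.
#' @param betas n_subjects x n_vertices per-subject maps (the permutation
#'   engine recomputes t from these).
#' @param cf_p Cluster-forming p threshold (one-sided), default 0.01.
#' @param alpha Cluster-level FWE threshold, default 0.05.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param seed Integer seed for the flips.
#' @param mask Logical vertex mask; defaults to the patch mask.
#' @return A `cluster_table` data frame sorted by corrected p: `cluster`,
#'   `size`, `peak_vertex`, `peak_x/y/z` (mm), `peak_ap`, `peak_t`,
#'   `p_fwe`; attribute `all_clusters` keeps the unthresholded table and
#'   `t_threshold` the cluster-forming cutoff.
#' @export
cluster_fwe <- function(tmap, patch, betas, cf_p = 0.01, alpha = 0.05,
                        n_perm = 1000, seed = 1, mask = patch$mask) {
  assert_that(n_perm >= 100, "n_perm must be >= 100")
  n_sub <- nrow(betas)
  df <- n_sub - 1
  t_thr <- stats::qt(1 - cf_p, df)
  adj <- patch_adjacency(patch)

  supra <- which(mask & !is.na(tmap) & tmap > t_thr)
  obs <- cluster_sizes(adj, supra)

  # permutation null of the maximum cluster size; t recomputed from the
  # per-subject maps under random sign flips (vectorized over vertices)
  midx <- which(mask)
  B <- betas[, midx, drop = FALSE]
  B2 <- colSums(B^2)
  null_max <- with_rng(seed, {
    vapply(seq_len(n_perm), function(p) {
      s <- sample(c(-1, 1), n_sub, replace = TRUE)
      m <- colSums(B * s) / n_sub
      sd2 <- pmax((B2 - n_sub * m^2) / (n_sub - 1), 0)
      tp <- ifelse(sd2 > 0, m / sqrt(sd2 / n_sub), 0)
      sup <- midx[!is.na(tp) & tp > t_thr]
      cs <- cluster_sizes(adj, sup)
      if (length(cs$size)) max(cs$size) else 0L
    }, numeric(1))
  })

  if (!length(obs$size)) {
    tab <- data.frame(cluster = integer(), size = integer(),
                      peak_vertex = integer(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      peak_ap = numeric(), peak_t = numeric(),
                      p_fwe = numeric())
  } else {
    peak <- vapply(obs$members, function(vs) vs[which.max(tmap[vs])],
                   integer(1))
    tab <- data.frame(
      cluster = seq_along(obs$size),
      size = obs$size,
      peak_vertex = peak,
      peak_x = patch$vertices[peak, 1],
      peak_y = patch$vertices[peak, 2],
      peak_z = patch$vertices[peak, 3],
      peak_ap = patch$ap_coord[peak],
      peak_t = tmap[peak],
      p_fwe = vapply(obs$size, function(s)
        (1 + sum(null_max >= s)) / (1 + n_perm), numeric(1))
    )
    tab <- tab[order(tab$p_fwe, -tab$size), , drop = FALSE]
    rownames(tab) <- NULL
  }
  out <- tab[tab$p_fwe <= alpha, , drop = FALSE]
  attr(out, "all_clusters") <- tab
  attr(out, "t_threshold") <- t_thr
  attr(out, "null_max") <- null_max
  class(out) <- c("cluster_table", class(out))
  out
}

# Sizes and member lists of connected components among `verts`.
cluster_sizes <- function(adj, verts) {
  if (!length(verts)) return(list(size = integer(), members = list()))
  lab <- mesh_components(adj, verts)
  labs <- lab[verts]
  members <- split(verts, labs)
  list(size = vapply(members, length, integer(1)), members = members)
}
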