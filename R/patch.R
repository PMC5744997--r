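#' Generate a template cortical patch
#'
#' Builds a rectangular strip of vertices triangulated into a single
#' connected mesh, folded along its long axis with a sinusoidal profile so
#' that signed curvature alternates like gyri and sulci. The long axis is
#' parameterized by `ap_coord` in \[0, 1\] (0 = posterior, 1 = anterior).
#' An elliptical interior subset of vertices forms the insular mask.
#'
#' @param n_vertices Requested vertex count (>= 50); realised as an
#'   `nu x nv` grid with `nv = max(4, round(sqrt(n_vertices / 6)))`.
#' @param seed Integer seed; the construction is deterministic given it.
#' @param length_mm,width_mm Physical extent of the strip in millimetres.
#' @param n_folds Number of gyral/sulcal cycles along the patch.
#' @param fold_amp_mm Amplitude of the sinusoidal fold.
#' @return A `cortical_patch`: `vertices` (n x 3, mm), `faces` (m x 3,
#'   1-based indices), `curvature`, `ap_coord`, `lat_coord`, `mask`
#'   (logical), grid dims `nu`, `nv`.
#' @export
make_template_patch <- function(n_vertices = 600, seed = 1,
                                length_mm = 60, width_mm = 9,
                                n_folds = 4, fold_amp_mm = 2) {
  assert_that(n_vertices >= 50, "n_vertices must be >= 50, got %d", n_vertices)
  nv <- max(4L, as.integer(round(sqrt(n_vertices / 6))))
  nu <- max(8L, as.integer(round(n_vertices / nv)))
  with_rng(seed, {
    ap <- rep((seq_len(nu) - 1) / (nu - 1), each = nv)
    lat <- rep((seq_len(nv) - 1) / (nv - 1), times = nu)
    z <- fold_amp_mm * sin(2 * pi * n_folds * ap)
    vertices <- cbind(x = ap * length_mm, y = lat * width_mm, z = z)
    curvature <- sin(2 * pi * n_folds * ap)

    # two triangles per grid cell
    faces <- matrix(0L, nrow = 2L * (nu - 1L) * (nv - 1L), ncol = 3L)
    k <- 0L
    idx <- function(i, j) (i - 1L) * nv + j  # i along ap, j lateral
    for (i in seq_len(nu - 1L)) {
      for (j in seq_len(nv - 1L)) {
        a <- idx(i, j); b <- idx(i + 1L, j)
        c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
        faces[k + 1L, ] <- c(a, b, c2)
        faces[k + 2L, ] <- c(a, c2, d)
        k <- k + 2L
      }
    }

    # elliptical insular mask in normalized (ap, lat) coordinates
    mask <- ((ap - 0.5) / 0.48)^2 + ((lat - 0.5) / 0.92)^2 <= 1

    out <- list(vertices = vertices, faces = faces, curvature = curvature,
                ap_coord = ap, lat_coord = lat, mask = mask,
                nu = nu, nv = nv)
    class(out) <- "cortical_patch"
    out
  })
}

#' @export
print.cortical_patch <- function(x, ...) {
  cat(sprintf("<cortical_patch> %d vertices (%d x %d grid), %d faces, %d in mask\n",
              nrow(x$vertices), x$nu, x$nv, nrow(x$faces), sum(x$mask)))
  invisible(x)
}

#' Vertex adjacency list of a patch
#'
#' Edge connectivity derived from the triangulation; used for smoothing,
#' cluster labeling and mesh connectivity checks.
#'
#' @param patch A `cortical_patch`.
#' @return List of integer vectors; element `v` holds the neighbours of `v`.
#' @export
patch_adjacency <- function(patch) {
  f <- patch$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(nrow(patch$vertices))))
}

# Label connected components of `subset` (logical or index vector) under an
# adjacency list. Returns integer labels (0 outside subset). Plain BFS kept
# dependency-free because it sits inside the permutation loop.
mesh_components <- function(adj, subset) {
  n <- length(adj)
  inset <- logical(n)
  if (is.logical(subset)) inset[subset] <- TRUE else inset[subset] <- TRUE
  labels <- integer(n)
  comp <- 0L
  for (v in which(inset)) {
    if (labels[v] > 0L) next
    comp <- comp + 1L
    queue <- v
    labels[v] <- comp
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[cur]]
      nb <- nb[inset[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- comp
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

# Is the face graph connected? (BFS over all vertices referenced by faces.)
patch_is_connected <- function(patch) {
  adj <- patch_adjacency(patch)
  lab <- mesh_components(adj, rep(TRUE, nrow(patch$vertices)))
  max(lab) == 1L
}

# Mean edge length (mm) of the mesh.
mean_edge_length <- function(patch) {
  f <- patch$faces
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)]))
  d <- patch$vertices[e[, 1], , drop = FALSE] - patch$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}
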