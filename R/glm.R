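#' Fit the mass-univariate GLM
#'
#' Ordinary-least-squares solve per vertex against the full design matrix.
#' The per-taste response estimate ("beta") is the coefficient of that
#' taste's canonical (non-derivative) regressor — the contrast of the taste
#' versus rest — with its standard error from the residual variance and the
#' contrast leverage. Rank-deficient designs are solved by pseudo-inverse
#' with a warning.
#'
#' @param recording A `subject_recording` (or any list with a `bold`
#'   matrix, n_vertices x n_volumes).
#' @param design A `design_matrix` sharing the recording's volume count.
#' @return A `beta_maps` object: `beta` and `se` (n_vertices x 6, canonical
#'   taste order), `subject_id`, `df_residual`.
#' @export
fit_glm <- function(recording, design) {
  Y <- t(recording$bold)             # time x vertices
  X <- design$matrix
  assert_that(nrow(Y) == nrow(X),
              "recording has %d volumes but design has %d rows",
              nrow(Y), nrow(X))
  if (anyNA(Y)) {
    all_na <- colSums(is.na(Y)) == nrow(Y)
    assert_that(!any(all_na), "all-NaN time series at %d vertex(es)",
                sum(all_na))
  }

  qrX <- qr(X)
  p <- ncol(X)
  if (qrX$rank < p) {
    warning(sprintf("design is rank-deficient (rank %d < %d); using pseudo-inverse",
                    qrX$rank, p))
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    Xpinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    coefs <- Xpinv %*% Y
    XtXinv_diag <- rowSums(Xpinv^2)
  } else {
    coefs <- qr.coef(qrX, Y)
    XtXinv_diag <- diag(chol2inv(chol(crossprod(X))))
  }

  fitted <- X %*% coefs
  res <- Y - fitted
  dfres <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / dfres

  tc <- design$taste_cols
  beta <- t(coefs[tc, , drop = FALSE])
  se <- sqrt(outer(sigma2, XtXinv_diag[tc]))
  colnames(beta) <- colnames(se) <- taste_labels()

  out <- list(beta = beta, se = se,
              subject_id = recording$subject_id %||% "unknown",
              df_residual = dfres)
  class(out) <- "beta_maps"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beta_maps <- function(x, ...) {
  cat(sprintf("<beta_maps> %s: %d vertices x %d tastes (df %d)\n",
              x$subject_id, nrow(x$beta), ncol(x$beta), x$df_residual))
  invisible(x)
}

#' Gaussian smoothing of a per-vertex map on the mesh
#'
#' Iterative neighbour averaging on the mesh graph. The number of
#' iterations is calibrated from the mesh geometry: one averaging step adds
#' per-axis positional variance `v1 = mean_i sum_j ||x_j - x_i||^2 / 2 /
#' (deg_i + 1)`, and iterations are repeated until the accumulated variance
#' reaches `(fwhm / 2.3548)^2`. `fwhm = 0` returns the input unchanged.
#' When a mask is given, smoothing is confined to (and renormalized over)
#' the masked vertices; disconnected mask regions are smoothed per
#' component.
#'
#' @param map Numeric vector (or n x k matrix of maps) over vertices.
#' @param patch A `cortical_patch`.
#' @param fwhm Full width at half maximum, mm.
#' @param mask Optional logical vector restricting the smoothing domain.
#' @return Smoothed map(s), same shape as `map`.
#' @export
smooth_map <- function(map, patch, fwhm = 8, mask = NULL) {
  assert_that(fwhm >= 0, "fwhm must be >= 0")
  vec_in <- is.null(dim(map))
  M <- if (vec_in) matrix(map, ncol = 1) else as.matrix(map)
  if (fwhm == 0) return(if (vec_in) M[, 1] else M)

  n <- nrow(patch$vertices)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  adj <- patch_adjacency(patch)

  # per-iteration variance increment from mesh geometry
  v1 <- mean(vapply(which(keep), function(i) {
    nb <- adj[[i]]
    nb <- nb[keep[nb]]
    if (!length(nb)) return(0)
    d <- patch$vertices[nb, , drop = FALSE] -
      matrix(patch$vertices[i, ], length(nb), 3, byrow = TRUE)
    sum(rowSums(d^2)) / 2 / (length(nb) + 1)
  }, numeric(1)))
  sigma2 <- (fwhm / 2.3548)^2
  n_iter <- max(1L, as.integer(round(sigma2 / v1)))

  # sparse row-normalized averaging operator over the masked subgraph
  ii <- unlist(lapply(which(keep), function(i) {
    nb <- adj[[i]]
    rep(i, sum(keep[nb]) + 1L)
  }))
  jj <- unlist(lapply(which(keep), function(i) c(i, adj[[i]][keep[adj[[i]]]])))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  rs <- Matrix::rowSums(A)
  A <- Matrix::Diagonal(n, x = 1 / pmax(rs, 1)) %*% A

  out <- M
  sm <- M
  sm[!keep, ] <- 0
  for (it in seq_len(n_iter)) sm <- as.matrix(A %*% sm)
  out[keep, ] <- sm[keep, ]
  if (vec_in) out[, 1] else out
}
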