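#' Plant a chemotopic ground-truth layout on a patch
#'
#' Each taste gets a smooth Gaussian bump of response amplitude centred at
#' equally spaced positions along `ap_coord`, in the given
#' posterior-to-anterior order. A cross-talk fraction mixes in the other
#' tastes' bumps, so every taste elicits some response everywhere inside the
#' mask (responses overlap, as real insular responses do); with
#' `overlap < 1` the per-vertex argmax taste is unchanged by the mixing.
#' Amplitudes are zero outside the mask.
#'
#' @param patch A `cortical_patch`.
#' @param ordering Permutation of the six taste labels, posterior first.
#' @param width Spatial spread (sd of the bump) in ap units.
#' @param overlap Cross-talk fraction in \[0, 1).
#' @param peak Peak response amplitude (arbitrary BOLD units).
#' @return A `taste_layout`: `amplitude` (n_vertices x 6, canonical taste
#'   order columns), `cluster_centers` (named, ap units), `cluster_width`,
#'   `overlap`, `ordering`, `peak`.
#' @export
plant_layout <- function(patch, ordering = planted_order(),
                         width = 0.08, overlap = 0.3, peak = 1) {
  assert_that(width > 0, "width must be positive")
  assert_that(overlap >= 0 && overlap < 1, "overlap must be in [0,1)")
  assert_that(setequal(ordering, taste_labels()) &&
                length(ordering) == 6, "ordering must permute the six tastes")

  centers <- stats::setNames((seq_along(ordering) - 0.5) / length(ordering),
                             ordering)[taste_labels()]
  amp <- layout_amplitude_at(patch$ap_coord, centers, width, overlap, peak)
  amp[!patch$mask, ] <- 0

  out <- list(amplitude = amp, cluster_centers = centers,
              cluster_width = width, overlap = overlap,
              ordering = ordering, peak = peak)
  class(out) <- "taste_layout"
  out
}

# Evaluate the bump-mixture amplitude at arbitrary ap coordinates.
# A_t = (1 - overlap) * B_t + overlap * sum_t' B_t'  (equivalently
# B_t + overlap * sum of the *other* bumps), preserving the argmax of B.
layout_amplitude_at <- function(ap, centers, width, overlap, peak) {
  B <- sapply(centers, function(c0) exp(-(ap - c0)^2 / (2 * width^2)))
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  S <- rowSums(B)
  peak * ((1 - overlap) * B + overlap * S)
}

#' Evaluate a layout's amplitude at given ap coordinates
#'
#' Used by the simulator to read the planted response at *warped*
#' (subject-anatomy) coordinates without resampling the template grid.
#'
#' @param layout A `taste_layout`.
#' @param ap Numeric vector of ap coordinates.
#' @return Matrix `length(ap) x 6` in canonical taste order.
#' @export
layout_amplitude <- function(layout, ap) {
  layout_amplitude_at(ap, layout$cluster_centers, layout$cluster_width,
                      layout$overlap, layout$peak)
}

#' @export
print.taste_layout <- function(x, ...) {
  cat(sprintf("<taste_layout> order %s; width %.3g, overlap %.2g, peak %.3g\n",
              paste(x$ordering, collapse = " > "),
              x$cluster_width, x$overlap, x$peak))
  invisible(x)
}
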