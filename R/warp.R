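#' Construct a monotone subject warp
#'
#' A warp maps the subject's anterior-posterior coordinate to the template
#' coordinate through a strictly increasing monotone piecewise-cubic
#' (Hermite) interpolant with endpoints anchored at 0 and 1.
#'
#' @param knots_x Strictly increasing subject-coordinate knots spanning
#'   \[0, 1\].
#' @param knots_u Strictly increasing template coordinates at the knots,
#'   with `knots_u[1] == 0` and `knots_u[length]` == 1`.
#' @return A `subject_warp` object.
#' @export
make_warp <- function(knots_x, knots_u) {
  assert_that(all(diff(knots_x) > 0) && all(diff(knots_u) > 0),
              "warp control points must be strictly increasing")
  assert_that(isTRUE(all.equal(range(knots_x), c(0, 1))) &&
                isTRUE(all.equal(range(knots_u), c(0, 1))),
              "warp endpoints must be anchored at 0 and 1")
  out <- list(knots_x = knots_x, knots_u = knots_u)
  class(out) <- "subject_warp"
  out
}

#' Identity warp
#' @param n_knots Number of control points.
#' @return A `subject_warp` equal to the identity map.
#' @export
identity_warp <- function(n_knots = 11) {
  g <- seq(0, 1, length.out = n_knots)
  make_warp(g, g)
}

#' Apply a warp (subject -> template coordinates)
#' @param warp A `subject_warp`.
#' @param x Subject ap coordinates in \[0, 1\].
#' @return Template ap coordinates.
#' @export
warp_apply <- function(warp, x) {
  f <- stats::splinefun(warp$knots_x, warp$knots_u, method = "monoH.FC")
  pmin(1, pmax(0, f(x)))
}

#' Invert a warp (template -> subject coordinates)
#'
#' Numerical inversion by dense sampling of the forward map followed by a
#' monotone re-fit with the roles of the axes exchanged.
#'
#' @param warp A `subject_warp`.
#' @param n_dense Number of samples used for the inversion.
#' @return A `subject_warp` representing the inverse map.
#' @export
warp_invert <- function(warp, n_dense = 400) {
  x <- seq(0, 1, length.out = n_dense)
  u <- warp_apply(warp, x)
  u[1] <- 0; u[n_dense] <- 1
  keep <- c(TRUE, diff(u) > 1e-12)
  make_warp(u[keep], x[keep])
}

#' Random smooth ground-truth warp
#'
#' Identity plus a low-order sinusoidal perturbation, rescaled so the
#' maximum displacement equals `max_disp` and monotonicity holds.
#'
#' @param max_disp Maximum |warp(x) - x| in ap units.
#' @param seed Integer seed.
#' @param n_knots Control points used to represent the warp.
#' @return A `subject_warp`.
#' @export
random_warp <- function(max_disp = 0.08, seed = 1, n_knots = 11) {
  with_rng(seed, {
    x <- seq(0, 1, length.out = 201)
    a <- stats::rnorm(3)
    pert <- a[1] * sin(pi * x) + a[2] * sin(2 * pi * x) + a[3] * sin(3 * pi * x)
    if (max(abs(pert)) > 0) pert <- pert / max(abs(pert)) * max_disp
    u <- x + pert
    # enforce strict monotonicity (max_disp < 1/(3*pi) keeps it automatic)
    u <- cummax(u + seq_along(u) * 1e-12)
    u <- (u - u[1]) / (u[length(u)] - u[1])
    g <- seq(0, 1, length.out = n_knots)
    make_warp(g, stats::approx(x, u, xout = g)$y)
  })
}

#' @export
print.subject_warp <- function(x, ...) {
  d <- max(abs(x$knots_u - x$knots_x))
  cat(sprintf("<subject_warp> %d control points, max displacement %.3g\n",
              length(x$knots_x), d))
  invisible(x)
}
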