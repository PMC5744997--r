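#' Binned curvature profile along the ap axis
#'
#' Mean signed curvature of the vertices falling in each of `n_bins`
#' equal-width bins of the ap coordinate. Empty bins are filled by linear
#' interpolation from their neighbours (with a message).
#'
#' @param ap Per-vertex ap coordinates in \[0, 1\].
#' @param curvature Per-vertex signed curvature values.
#' @param n_bins Number of bins (>= 4).
#' @return List with `centers` (bin centres) and `profile` (mean curvature).
#' @export
curvature_profile <- function(ap, curvature, n_bins = 48) {
  assert_that(n_bins >= 4, "n_bins must be >= 4")
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(ap, br, include.lowest = TRUE, labels = FALSE)
  prof <- tapply(curvature, factor(bin, levels = seq_len(n_bins)), mean)
  prof <- as.numeric(prof)
  if (anyNA(prof)) {
    message(sprintf("curvature_profile: interpolating %d empty bin(s)",
                    sum(is.na(prof))))
    ok <- which(!is.na(prof))
    prof <- stats::approx(ok, prof[ok], xout = seq_len(n_bins), rule = 2)$y
  }
  list(centers = (br[-1] + br[-length(br)]) / 2, profile = prof)
}

#' Curvature profile of a patch
#'
#' Convenience wrapper of [curvature_profile()] for a `cortical_patch` or a
#' `subject_recording` (which carries the subject's warped curvature).
#'
#' @param x A `cortical_patch`, or a list with `ap_coord`/`curvature`.
#' @param n_bins Number of ap bins.
#' @return See [curvature_profile()].
#' @export
patch_profile <- function(x, n_bins = 48) {
  curvature_profile(x$ap_coord, x$curvature, n_bins)
}

# Evaluate a binned profile at arbitrary ap positions.
profile_at <- function(prof, ap) {
  stats::approx(prof$centers, prof$profile, xout = ap, rule = 2)$y
}

# Gaussian smoothing of a binned profile (sd in bins); sd 0 = identity.
smooth_profile <- function(prof, sd_bins) {
  if (sd_bins <= 0) return(prof)
  n <- length(prof$profile)
  half <- ceiling(3 * sd_bins)
  k <- stats::dnorm(-half:half, sd = sd_bins)
  padded <- c(rep(prof$profile[1], half), prof$profile,
              rep(prof$profile[n], half))
  sm <- stats::filter(padded, k / sum(k), sides = 2)[(half + 1):(half + n)]
  list(centers = prof$centers, profile = as.numeric(sm))
}

#' Moving-target curvature alignment
#'
#' Registers per-subject curvature profiles into a common space using only
#' the folding pattern. The procedure has two phases. (1) Initialization:
#' the most "central" subject is picked (highest mean profile correlation
#' with the rest) and every subject is registered pairwise to its profile;
#' the warps are then re-centred so the cohort-mean warp is the identity
#' (the only gauge a template-free groupwise registration can anchor to).
#' (2) Moving target: the aligned profiles are averaged into a dynamically
#' updated target and every subject's warp is re-optimized against it,
#' re-centring after each round, until the residual curvature variance
#' stops improving.
#'
#' Warps are monotone piecewise-cubic maps with anchored endpoints,
#' optimized by coordinate descent over their control points: each
#' interior knot is line-searched over a bounded candidate grid strictly
#' between its neighbours, so every proposal is monotone by construction.
#' The objective is the mean squared curvature mismatch plus
#' `smoothness` times a bending energy (mean squared second derivative of
#' the warp).
#'
#' @param profiles List of per-subject curvature profiles (as from
#'   [patch_profile()]), all on the same bin grid.
#' @param n_iter Maximum number of moving-target rounds.
#' @param smoothness Bending-energy weight (regularization).
#' @param n_knots Number of warp control points (including endpoints).
#' @param tol Stop when the residual-variance reduction falls below this.
#' @param recenter Re-center the warps after initialization and each round
#'   so the cohort-mean warp is the identity (default TRUE).
#' @return An `alignment_result`: `warps` (per-subject `subject_warp`,
#'   subject -> template), `template_profile` (aligned average curvature on
#'   the bin grid), `convergence` (residual curvature variance; entry 1 =
#'   unaligned, entry 2 = after initialization, then one per round),
#'   `central_subject`.
#' @export
moving_target_align <- function(profiles, n_iter = 10, smoothness = 1e-3,
                                n_knots = 11, tol = 1e-6, recenter = TRUE) {
  n_sub <- length(profiles)
  assert_that(n_sub >= 2, "alignment needs >= 2 subjects")
  u_grid <- profiles[[1]]$centers
  for (p in profiles)
    assert_that(isTRUE(all.equal(p$centers, u_grid)),
                "profiles must share the bin grid")

  # inverse warps g_s: template u -> subject x; the aligned profile is
  # p_s(g_s(u)). Each g_s is stored as its knot values (monotone, 0/1
  # endpoints anchored).
  knots_u <- seq(0, 1, length.out = n_knots)
  V <- matrix(rep(knots_u, n_sub), n_knots, n_sub)  # knot values per subject

  aligned_prof <- function(prof, v) {
    g <- stats::splinefun(knots_u, v, method = "monoH.FC")
    profile_at(prof, g(u_grid))
  }
  bending <- function(v) {
    d2 <- diff(diff(v)) * (n_knots - 1)^2   # ~ second derivative of g
    mean(d2^2)
  }
  obj_fn <- function(prof, target) function(vv)
    mean((aligned_prof(prof, vv) - target)^2) + smoothness * bending(vv)
  optimize_warp <- function(prof, target, v, sweeps, n_cand) {
    obj <- obj_fn(prof, target)
    best <- obj(v)
    for (sweep in seq_len(sweeps)) {
      for (k in 2:(n_knots - 1)) {
        cand <- seq(v[k - 1], v[k + 1], length.out = n_cand + 2)[-c(1, n_cand + 2)]
        for (cv in cand) {
          vv <- v; vv[k] <- cv
          val <- obj(vv)
          if (val < best) { best <- val; v <- vv }
        }
      }
    }
    v
  }
  # multi-start registration: seed the coordinate descent from a fan of
  # smooth global shifts so a subject displaced by a sizeable fraction of
  # the folding period cannot lock onto the wrong gyrus
  register_multistart <- function(prof, target,
                                  shifts = seq(-0.2, 0.2, by = 0.04)) {
    obj <- obj_fn(prof, target)
    best_v <- NULL
    best_val <- Inf
    for (d in shifts) {
      v0 <- knots_u + d * sin(pi * knots_u)
      v0 <- (cummax(v0 + seq_len(n_knots) * 1e-12) - min(v0)) /
        (max(v0) - min(v0))
      v <- optimize_warp(prof, target, v0, sweeps = 4L, n_cand = 21L)
      val <- obj(v)
      if (val < best_val) { best_val <- val; best_v <- v }
    }
    best_v
  }
  recenter_warps <- function(V) {
    gmean <- rowMeans(V)
    if (max(abs(gmean - knots_u)) < 1e-9) return(V)
    minv <- stats::splinefun(gmean, knots_u, method = "monoH.FC")
    at <- pmin(1, pmax(0, minv(knots_u)))
    apply(V, 2, function(v) {
      w <- stats::approx(knots_u, v, xout = at, rule = 2)$y
      w <- cummax(w + seq_len(n_knots) * 1e-12)
      (w - w[1]) / (w[n_knots] - w[1])
    })
  }
  resid_var <- function(mats) mean(apply(mats, 2, stats::var))
  aligned_all <- function() t(vapply(seq_len(n_sub), function(s)
    aligned_prof(profiles[[s]], V[, s]), numeric(length(u_grid))))

  convergence <- resid_var(aligned_all())

  # --- phase 1: pairwise registration to the most central subject
  P <- vapply(profiles, `[[`, numeric(length(u_grid)), "profile")
  cm <- stats::cor(P)
  diag(cm) <- NA
  central <- which.max(colMeans(cm, na.rm = TRUE))
  # subjects join the average in order of centrality, each registered
  # against the consensus of those already aligned: a new subject then
  # faces only its own displacement from the group, never the (up to
  # twice larger) displacement between two individual subjects
  joined <- central
  for (s in order(colMeans(cm, na.rm = TRUE), decreasing = TRUE)) {
    if (s == central) next
    target <- rowMeans(vapply(joined, function(j)
      aligned_prof(profiles[[j]], V[, j]), numeric(length(u_grid))))
    V[, s] <- register_multistart(profiles[[s]], target,
                                  shifts = seq(-0.12, 0.12, by = 0.03))
    joined <- c(joined, s)
    # keep the consensus gauge at the running cohort mean, so each next
    # joiner faces only its own anatomical displacement
    if (recenter)
      V[, joined] <- recenter_warps(V[, joined, drop = FALSE])
  }
  A <- aligned_all()
  convergence <- c(convergence, resid_var(A))

  # --- phase 2: moving-target refinement
  prev <- convergence[length(convergence)]
  for (it in seq_len(n_iter)) {
    target <- colMeans(A)
    mismatch <- vapply(seq_len(n_sub), function(s)
      mean((A[s, ] - target)^2), numeric(1))
    med_mis <- stats::median(mismatch)
    for (s in seq_len(n_sub)) {
      V[, s] <- if (mismatch[s] > 4 * med_mis && med_mis > 0)
        register_multistart(profiles[[s]], target)  # rescue a misfit
      else
        optimize_warp(profiles[[s]], target, V[, s],
                      sweeps = 2L, n_cand = 13L)
    }
    if (recenter) V <- recenter_warps(V)
    A <- aligned_all()
    rv <- resid_var(A)
    convergence <- c(convergence, rv)
    if (prev - rv < tol) break
    prev <- rv
  }

  warps <- lapply(seq_len(n_sub), function(s) {
    # g_s maps template -> subject; invert to get subject -> template
    warp_invert(make_warp(knots_u, V[, s]))
  })
  out <- list(warps = warps,
              template_profile = list(centers = u_grid,
                                      profile = colMeans(A)),
              convergence = convergence, central_subject = central)
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d subjects, %d iterations, residual var %.3g -> %.3g\n",
              length(x$warps), length(x$convergence) - 1,
              x$convergence[1], x$convergence[length(x$convergence)]))
  invisible(x)
}

#' Resample a subject map onto the template
#'
#' Pulls subject per-vertex values back to the template vertices through
#' the subject's warp: the template vertex at ap coordinate `u` reads the
#' subject map at subject coordinate `warp^{-1}(u)`, with linear
#' interpolation along the ap axis within each lateral row of the strip.
#'
#' @param map Per-vertex values on the subject patch (vector or n x k
#'   matrix).
#' @param warp The subject's `subject_warp` (subject -> template).
#' @param template The template `cortical_patch` (topology shared with the
#'   subject patch).
#' @return Values on the template vertices, same shape as `map`.
#' @export
resample_map <- function(map, warp, template) {
  vec_in <- is.null(dim(map))
  M <- if (vec_in) matrix(map, ncol = 1) else as.matrix(map)
  inv <- warp_invert(warp)
  x_lookup <- warp_apply(inv, template$ap_coord)  # subject coords to read
  out <- M
  nv <- template$nv
  for (j in seq_len(nv)) {
    row_idx <- seq(j, nrow(M), by = nv)  # one lateral row of the strip
    ap_row <- template$ap_coord[row_idx]
    o <- order(ap_row)
    for (k in seq_len(ncol(M))) {
      out[row_idx, k] <- stats::approx(ap_row[o], M[row_idx[o], k],
                                       xout = x_lookup[row_idx],
                                       rule = 2, ties = mean)$y
    }
  }
  if (vec_in) out[, 1] else out
}

#' Vertex-wise group average of aligned maps
#'
#' @param maps List of per-vertex matrices (or vectors), one per subject,
#'   already resampled onto the template.
#' @return The arithmetic mean, same shape as the inputs.
#' @export
group_average <- function(maps) {
  assert_that(length(maps) >= 1, "group_average needs >= 1 subject")
  Reduce(`+`, maps) / length(maps)
}
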