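#' Analytic GLM noise calibration
#'
#' Standard error of a taste beta under the default design is
#' `sigma * sqrt((X'X)^-1_tt)`; this helper returns the `sigma` that makes
#' the per-vertex contrast-to-noise ratio (peak planted amplitude over
#' beta s.e.) equal `cnr` for the given schedule and HRF.
#'
#' @param schedule A `stim_schedule`.
#' @param hrf An `hrf_kernel`.
#' @param peak Peak planted amplitude.
#' @param cnr Target contrast-to-noise ratio.
#' @return Noise sigma (per-volume sd).
#' @export
calibrate_sigma <- function(schedule, hrf = canonical_hrf(), peak = 1,
                            cnr = 1.5) {
  d <- build_design_matrix(schedule, hrf, motion = NULL)
  XtXinv <- chol2inv(chol(crossprod(d$matrix)))
  lev <- mean(diag(XtXinv)[d$taste_cols])
  peak / (cnr * sqrt(lev))
}

#' Default run configuration
#'
#' Collects every tunable of the pipeline in one nested list: protocol
#' timings, mesh and layout parameters, noise, GLM options, QC thresholds,
#' alignment options, prevalence options and permutation counts. The noise
#' sigma defaults to the value giving a per-vertex CNR of `cnr` under the
#' default design (see [calibrate_sigma()]).
#'
#' @param seed Global seed; all per-stage seeds derive from it.
#' @param n_subjects Cohort size (default 10, of which `n_violators` carry
#'   excluded-level motion).
#' @param n_vertices Patch size.
#' @param cnr Target contrast-to-noise ratio for the default noise level.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1, n_subjects = 10, n_vertices = 600,
                           cnr = 1.5) {
  schedule <- build_schedule()
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    n_violators = 2L,
    protocol = list(tr = 2, timing = default_timing(),
                    sequences = default_sequences()),
    patch = list(n_vertices = as.integer(n_vertices), length_mm = 60,
                 width_mm = 9, n_folds = 4, fold_amp_mm = 2),
    layout = list(ordering = planted_order(), width = 0.08,
                  overlap = 0.3, peak = 1),
    noise = list(sigma = calibrate_sigma(schedule, peak = 1, cnr = cnr),
                 ar1_rho = 0.3, drift_amp = 0.5),
    warp = list(max_disp = 0.08),
    glm = list(hp_cutoff = 128, fwhm = 8, include_swallow = FALSE,
               nuisance_frac = 0.5),
    qc = list(trans_thresh = 1, rot_thresh = 1),
    alignment = list(n_iter = 20, smoothness = 1e-3, n_knots = 11,
                     n_bins = 48),
    prevalence = list(saturation_cap = 200, clarity_min = 5,
                      group_mode = "average_betas"),
    inference = list(cf_p = 0.01, alpha = 0.05, n_perm = 1000),
    similarity = list(n_perm = 500)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$layout$ordering <- as.character(cfg$layout$ordering)
  cfg$protocol$sequences <- lapply(cfg$protocol$sequences, as.character)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Simulate a full synthetic cohort
#'
#' Builds the schedule, template patch, planted layout, per-subject
#' ground-truth warps and BOLD recordings (the last `n_violators` subjects
#' get excluded-level motion). Optionally writes everything to disk in the
#' package's text formats.
#'
#' @param config A `run_config`, see [default_config()].
#' @param out_dir Optional directory; when given, events TSV, patch TSV,
#'   per-subject BOLD NIfTI + motion TSV, warps JSON and a manifest JSON
#'   are written there.
#' @return A `cohort` list: `schedule`, `patch`, `layout`, `hrf`,
#'   `recordings` (list of `subject_recording`), `config`.
#' @export
simulate_cohort <- function(config = default_config(), out_dir = NULL) {
  schedule <- build_schedule(config$protocol$sequences,
                             config$protocol$timing, config$protocol$tr)
  patch <- make_template_patch(config$patch$n_vertices, seed = config$seed,
                               length_mm = config$patch$length_mm,
                               width_mm = config$patch$width_mm,
                               n_folds = config$patch$n_folds,
                               fold_amp_mm = config$patch$fold_amp_mm)
  layout <- plant_layout(patch, config$layout$ordering, config$layout$width,
                         config$layout$overlap, config$layout$peak)
  hrf <- canonical_hrf()

  n_sub <- config$n_subjects
  sub_seeds <- with_rng(config$seed,
                        sample.int(.Machine$integer.max, 2 * n_sub))
  recordings <- lapply(seq_len(n_sub), function(s) {
    violator <- s > n_sub - config$n_violators
    warp <- random_warp(config$warp$max_disp, seed = sub_seeds[s])
    simulate_subject(layout, patch, schedule, hrf, warp,
                     noise = config$noise,
                     nuisance_frac = config$glm$nuisance_frac,
                     motion_severity = if (violator) "excluded" else "compliant",
                     subject_id = sprintf("sub-%02d", s),
                     seed = sub_seeds[n_sub + s])
  })

  cohort <- list(schedule = schedule, patch = patch, layout = layout,
                 hrf = hrf, recordings = recordings, config = config)
  class(cohort) <- "cohort"
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

# Serialize a cohort to disk in the package text/NIfTI formats.
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events_tsv(cohort$schedule, file.path(out_dir, "events.tsv"))
  write_patch_tsv(cohort$patch, file.path(out_dir, "patch"))
  write_warps_json(lapply(cohort$recordings, `[[`, "warp"),
                   file.path(out_dir, "warps_true.json"))
  write_map_tsv(cohort$layout$amplitude,
                file.path(out_dir, "layout_amplitude.tsv"))
  for (r in cohort$recordings) {
    write_bold_nifti(r$bold,
                     file.path(out_dir, paste0(r$subject_id, "_bold.nii.gz")),
                     tr = cohort$schedule$tr)
    write_motion_tsv(r$motion,
                     file.path(out_dir, paste0(r$subject_id, "_motion.tsv")))
  }
  jsonlite::write_json(
    list(n_subjects = length(cohort$recordings),
         subject_ids = vapply(cohort$recordings, `[[`, "", "subject_id"),
         seed = cohort$config$seed),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Run the full analysis pipeline on a cohort
#'
#' QC (motion exclusion) -> per-subject GLM and surface smoothing ->
#' moving-target curvature alignment and resampling onto the template ->
#' group averaging -> per-taste random-effects cluster statistics ->
#' group and per-subject prevalence maps (optionally with one taste
#' excluded) -> individual-to-group similarity.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param exclude_taste Optional taste label; when given, an additional
#'   prevalence map without that taste (with "unassigned" vertices) is
#'   computed.
#' @param stop_after One of `"qc"`, `"glm"`, `"align"`, `"group"`,
#'   `"prevalence"`, `"all"`: stage gating for partial runs.
#' @param out_dir Optional directory for result TSVs.
#' @return A `pipeline_result` list with (depending on `stop_after`):
#'   `qc`, `betas` (per kept subject, smoothed), `alignment`,
#'   `aligned_betas`, `group_beta`, `cluster_tables` (per taste),
#'   `group_z`, `group_pmap`, `pmap_excluded`, `subject_pmaps`,
#'   `similarity`, `config`.
#' @export
run_pipeline <- function(cohort, exclude_taste = NULL,
                         stop_after = c("all", "qc", "glm", "align",
                                        "group", "prevalence"),
                         out_dir = NULL) {
  stop_after <- match.arg(stop_after)
  config <- cohort$config
  patch <- cohort$patch
  res <- list(config = config)
  class(res) <- "pipeline_result"

  qc <- motion_exclusion(cohort$recordings, config$qc$trans_thresh,
                         config$qc$rot_thresh)
  res$qc <- qc
  kept <- attr(qc, "kept")
  assert_that(length(kept) >= 2,
              "fewer than 2 subjects remain after motion exclusion")
  recs <- cohort$recordings[kept]
  if (stop_after == "qc") return(finish_pipeline(res, out_dir))

  hrf <- cohort$hrf
  res$betas <- lapply(recs, function(r) {
    design <- build_design_matrix(cohort$schedule, hrf, motion = r$motion,
                                  hp_cutoff = config$glm$hp_cutoff,
                                  include_swallow = config$glm$include_swallow)
    bm <- fit_glm(r, design)
    # smooth within the mask: unmasked neighbours carry no planted signal,
    # and letting them bleed in attenuates boundary-adjacent clusters.
    # Off-mask vertices are zeroed so later resampling never interpolates
    # raw unsmoothed noise into boundary vertices.
    bm$beta <- smooth_map(bm$beta, patch, config$glm$fwhm,
                          mask = patch$mask)
    bm$beta[!patch$mask, ] <- 0
    bm
  })
  if (stop_after == "glm") return(finish_pipeline(res, out_dir))

  profiles <- lapply(recs, function(r)
    curvature_profile(patch$ap_coord, r$curvature,
                      config$alignment$n_bins))
  res$alignment <- moving_target_align(profiles,
                                       n_iter = config$alignment$n_iter,
                                       smoothness = config$alignment$smoothness,
                                       n_knots = config$alignment$n_knots)
  res$aligned_betas <- lapply(seq_along(recs), function(s)
    resample_map(res$betas[[s]]$beta, res$alignment$warps[[s]], patch))
  if (stop_after == "align") return(finish_pipeline(res, out_dir))

  res$group_beta <- group_average(res$aligned_betas)
  perm_seeds <- with_rng(config$seed + 1L, sample.int(2^30, 6))
  res$cluster_tables <- lapply(stats::setNames(seq_along(taste_labels()),
                                               taste_labels()), function(j) {
    sub_mat <- do.call(rbind, lapply(res$aligned_betas, function(b) b[, j]))
    tmap <- group_ttest(sub_mat, mask = patch$mask)
    cluster_fwe(tmap, patch, sub_mat, cf_p = config$inference$cf_p,
                alpha = config$inference$alpha,
                n_perm = config$inference$n_perm, seed = perm_seeds[j])
  })
  if (stop_after == "group") return(finish_pipeline(res, out_dir))

  res$group_z <- group_prevalence_z(res$aligned_betas, res$group_beta,
                                    patch$mask,
                                    mode = config$prevalence$group_mode)
  res$group_pmap <- rank_and_win(res$group_z,
                                 config$prevalence$saturation_cap)
  if (!is.null(exclude_taste))
    res$pmap_excluded <- exclude_taste_remap(
      res$group_z, exclude_taste, config$prevalence$clarity_min,
      config$prevalence$saturation_cap)
  res$subject_pmaps <- lapply(res$aligned_betas, function(b)
    rank_and_win(zscore_maps(b, patch$mask),
                 config$prevalence$saturation_cap))
  if (stop_after == "prevalence") return(finish_pipeline(res, out_dir))

  res$similarity <- similarity_analysis(
    res$aligned_betas, res$subject_pmaps, res$group_beta, res$group_pmap,
    patch$mask, n_perm = config$similarity$n_perm,
    seed = config$seed + 2L)
  finish_pipeline(res, out_dir)
}

#' Group-level z maps for prevalence mapping
#'
#' Default mode z-scores the group-averaged aligned beta maps over the
#' mask; the alternative averages the per-subject z maps instead.
#'
#' @param aligned_betas List of per-subject aligned beta matrices.
#' @param group_beta Group-average beta matrix.
#' @param mask Logical vertex mask.
#' @param mode `"average_betas"` (default) or `"average_z"`.
#' @return A `zscore_maps` object.
#' @export
group_prevalence_z <- function(aligned_betas, group_beta, mask,
                               mode = c("average_betas", "average_z")) {
  mode <- match.arg(mode)
  if (mode == "average_betas") return(zscore_maps(group_beta, mask))
  zs <- lapply(aligned_betas, function(b) zscore_maps(b, mask)$z)
  out <- list(z = Reduce(`+`, zs) / length(zs), mask = mask)
  class(out) <- "zscore_maps"
  out
}

# Write pipeline outputs that exist; return the result.
finish_pipeline <- function(res, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$qc))
      data.table::fwrite(res$qc, file.path(out_dir, "qc_report.tsv"),
                         sep = "\t")
    if (!is.null(res$cluster_tables)) {
      tab <- do.call(rbind, lapply(names(res$cluster_tables), function(t) {
        ct <- attr(res$cluster_tables[[t]], "all_clusters")
        if (nrow(ct)) cbind(taste = t, ct) else NULL
      }))
      if (!is.null(tab))
        data.table::fwrite(tab, file.path(out_dir, "cluster_table.tsv"),
                           sep = "\t")
    }
    if (!is.null(res$group_pmap))
      write_prevalence_tsv(res$group_pmap,
                           file.path(out_dir, "prevalence_group.tsv"))
    if (!is.null(res$pmap_excluded))
      write_prevalence_tsv(res$pmap_excluded,
                           file.path(out_dir, "prevalence_excluded.tsv"))
    if (!is.null(res$similarity)) {
      data.table::fwrite(res$similarity$pearson,
                         file.path(out_dir, "similarity_pearson.tsv"),
                         sep = "\t")
      data.table::fwrite(res$similarity$spearman,
                         file.path(out_dir, "similarity_spearman.tsv"),
                         sep = "\t")
    }
    jsonlite::write_json(list(seed = res$config$seed,
                              package_version = as.character(
                                utils::packageVersion("tastemap"))),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  res
}
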