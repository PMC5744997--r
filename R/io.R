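#' Write / read a stimulation schedule as a BIDS-style events TSV
#'
#' Columns: `onset`, `duration`, `trial_type`, `volume_ml`; schedule-level
#' fields (`tr`, `n_volumes`, timing) travel in a JSON sidecar.
#'
#' @param schedule A `stim_schedule`.
#' @param path Output TSV path (`.json` sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  ev <- schedule$events
  names(ev)[names(ev) == "label"] <- "trial_type"
  data.table::fwrite(ev, path, sep = "\t")
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(tr = schedule$tr, n_volumes = schedule$n_volumes,
         total_duration = schedule$total_duration,
         total_volume_ml = schedule$total_volume_ml,
         timing = schedule$timing, sequences = schedule$sequences),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- as.data.frame(data.table::fread(path, sep = "\t"))
  names(ev)[names(ev) == "trial_type"] <- "label"
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  out <- list(events = ev, tr = meta$tr,
              n_volumes = as.integer(meta$n_volumes),
              total_duration = meta$total_duration,
              total_volume_ml = meta$total_volume_ml,
              timing = as.list(meta$timing),
              sequences = lapply(meta$sequences, as.character))
  class(out) <- "stim_schedule"
  out
}

#' Write / read a cortical patch as plain-text TSV
#'
#' Two files: `<path>_vertices.tsv` (x, y, z, curvature, ap_coord,
#' lat_coord, mask) and `<path>_faces.tsv` (v1, v2, v3); grid dimensions in
#' a JSON sidecar.
#'
#' @param patch A `cortical_patch`.
#' @param path Path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_patch_tsv <- function(patch, path) {
  vt <- data.frame(patch$vertices, curvature = patch$curvature,
                   ap_coord = patch$ap_coord, lat_coord = patch$lat_coord,
                   mask = as.integer(patch$mask))
  data.table::fwrite(vt, paste0(path, "_vertices.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(patch$faces),
                     paste0(path, "_faces.tsv"), sep = "\t")
  jsonlite::write_json(list(nu = patch$nu, nv = patch$nv),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_patch_tsv
#' @export
read_patch_tsv <- function(path) {
  vt <- as.data.frame(data.table::fread(paste0(path, "_vertices.tsv")))
  fc <- as.matrix(as.data.frame(data.table::fread(paste0(path, "_faces.tsv"))))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- list(vertices = as.matrix(vt[, c("x", "y", "z")]),
              faces = matrix(as.integer(fc), ncol = 3,
                             dimnames = NULL),
              curvature = vt$curvature, ap_coord = vt$ap_coord,
              lat_coord = vt$lat_coord, mask = vt$mask == 1L,
              nu = as.integer(meta$nu), nv = as.integer(meta$nv))
  class(out) <- "cortical_patch"
  out
}

#' Write / read motion traces as a 6-column TSV
#'
#' Columns: three translations (voxel units) then three rotations
#' (degrees); one row per volume.
#'
#' @param motion 6 x n_volumes matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_motion_tsv <- function(motion, path) {
  data.table::fwrite(as.data.frame(t(motion)), path, sep = "\t")
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  m <- t(as.matrix(as.data.frame(data.table::fread(path))))
  rownames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Write / read a per-vertex map (or map stack) as TSV
#'
#' @param map Vector or matrix of per-vertex values; column names kept.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  M <- if (is.null(dim(map))) data.frame(value = map) else as.data.frame(map)
  data.table::fwrite(M, path, sep = "\t")
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  M <- as.matrix(as.data.frame(data.table::fread(path)))
  if (ncol(M) == 1) as.numeric(M[, 1]) else M
}

#' Write a BOLD recording as NIfTI (vertices x 1 x 1 x time)
#'
#' Surface time series stored in the conventional flat-NIfTI layout, with
#' the TR recorded in the time-dimension pixdim.
#'
#' @param bold n_vertices x n_volumes matrix.
#' @param path Output `.nii.gz` path.
#' @param tr Repetition time, seconds.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path, tr = 2) {
  arr <- array(bold, dim = c(nrow(bold), 1, 1, ncol(bold)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  matrix(arr, nrow = dim(arr)[1], ncol = dim(arr)[4])
}

#' Write / read subject warps as JSON control-point arrays
#'
#' @param warps List of `subject_warp` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_warps_json <- function(warps, path) {
  jsonlite::write_json(
    lapply(warps, function(w) list(knots_x = w$knots_x,
                                   knots_u = w$knots_u)),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_warps_json
#' @export
read_warps_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(w) make_warp(unlist(w$knots_x), unlist(w$knots_u)))
}

#' Write a prevalence map as TSV
#'
#' One row per vertex: `vertex`, `in_mask`, `winner`, `saturation`, one
#' `pref_<taste>` column per taste.
#'
#' @param pmap A `prevalence_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_prevalence_tsv <- function(pmap, path) {
  prefs <- as.data.frame(pmap$normalized_pref)
  names(prefs) <- paste0("pref_", pmap$tastes)
  df <- cbind(data.frame(vertex = seq_along(pmap$winner),
                         in_mask = as.integer(pmap$mask),
                         winner = ifelse(is.na(pmap$winner), "", pmap$winner),
                         saturation = pmap$saturation), prefs)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
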