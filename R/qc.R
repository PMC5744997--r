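#' Motion-based subject exclusion
#'
#' A subject is excluded iff the maximum absolute head translation exceeds
#' `trans_thresh` (in units of the in-plane voxel size) **or** the maximum
#' absolute rotation exceeds `rot_thresh` degrees — strictly "more than",
#' so a trace touching the threshold exactly is kept. The excursion is
#' measured as the maximum absolute deviation from the reference (first)
#' volume's zero baseline.
#'
#' @param recordings List of `subject_recording` objects (or any objects
#'   with a 6 x n `motion` matrix and a `subject_id`).
#' @param trans_thresh Translation threshold, voxels (default 1).
#' @param rot_thresh Rotation threshold, degrees (default 1).
#' @return Data frame with `subject_id`, `max_translation`, `max_rotation`,
#'   `decision` ("keep"/"exclude"); attribute `kept` holds the indices of
#'   retained subjects.
#' @export
motion_exclusion <- function(recordings, trans_thresh = 1, rot_thresh = 1) {
  assert_that(length(recordings) > 0, "empty cohort")
  rows <- lapply(seq_along(recordings), function(i) {
    r <- recordings[[i]]
    assert_that(!is.null(r$motion) && nrow(r$motion) == 6,
                "subject %d lacks 6-row motion traces", i)
    mt <- max(abs(r$motion[1:3, ]))
    mr <- max(abs(r$motion[4:6, ]))
    data.frame(subject_id = r$subject_id %||% paste0("sub-", i),
               max_translation = mt, max_rotation = mr,
               decision = if (mt > trans_thresh || mr > rot_thresh)
                 "exclude" else "keep",
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  kept <- which(rep_df$decision == "keep")
  assert_that(length(kept) > 0, "all subjects excluded by the motion rule")
  attr(rep_df, "kept") <- kept
  rep_df
}
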