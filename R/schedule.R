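#' Default tastant delivery sequences
#'
#' The four pseudo-random orderings (A-D) in which the six tastants are
#' delivered; each sequence is a permutation of the six tastes and the four
#' sequences are run back to back, so every tastant occurs four times.
#'
#' @return Named list of four character vectors.
#' @export
default_sequences <- function() {
  list(
    A = c("co2", "umami", "sweet", "sour", "bitter", "salt"),
    B = c("bitter", "sweet", "salt", "co2", "sour", "umami"),
    C = c("bitter", "co2", "sweet", "umami", "sour", "salt"),
    D = c("sweet", "bitter", "sour", "co2", "salt", "umami")
  )
}

#' Default event-phase timing (seconds)
#'
#' Each liquid event is: 2 s delivery (5 ml at 2.5 ml/s, announced by an
#' auditory cue), 10 s tasting, a second cue plus 3 s swallow, then 15 s
#' rest; every tastant event is followed by a rinse-water event with the
#' identical phase structure.
#'
#' @return Named list with `delivery`, `tasting`, `swallow`, `rest`,
#'   `cue` (cue marker duration) and `volume_ml` per liquid event.
#' @export
default_timing <- function() {
  list(delivery = 2, tasting = 10, swallow = 3, rest = 15,
       cue = 0.5, volume_ml = 5)
}

#' Build the stimulation schedule
#'
#' Expands tastant orderings into a full experiment timeline. For each
#' tastant event the timeline contains: a cue at delivery onset, the liquid
#' event (delivery phase), a cue at swallow onset, the swallow event, and a
#' rest period; the identical structure follows immediately for the paired
#' rinse-water event.
#'
#' @param sequences List of character vectors; each must be a permutation of
#'   the six taste labels (or, for reduced designs, a subset of them).
#' @param timing Named list of phase durations, see [default_timing()].
#' @param tr Repetition time in seconds per acquired volume.
#' @return A `stim_schedule` object: data frame of events (`onset`,
#'   `duration`, `label`, `volume_ml`) plus `tr`, `n_volumes`, `timing`,
#'   `sequences` and `total_volume_ml` attributes.
#' @export
build_schedule <- function(sequences = default_sequences(),
                           timing = default_timing(),
                           tr = 2) {
  assert_that(tr > 0, "tr must be positive, got %s", tr)
  labs <- unique(unlist(sequences))
  bad <- setdiff(labs, taste_labels())
  assert_that(length(bad) == 0, "unknown tastant label(s): %s",
              paste(bad, collapse = ", "))
  for (nm in c("delivery", "tasting", "swallow", "rest"))
    assert_that(timing[[nm]] > 0, "timing$%s must be positive", nm)

  per_event <- timing$delivery + timing$tasting + timing$swallow + timing$rest
  tastants <- unlist(sequences, use.names = FALSE)

  rows <- vector("list", length(tastants) * 2L)
  t0 <- 0
  k <- 0L
  for (tst in tastants) {
    for (lab in c(tst, "water")) {  # tastant, then its rinse-water twin
      k <- k + 1L
      rows[[k]] <- data.frame(
        onset = c(t0, t0, t0 + timing$delivery + timing$tasting,
                  t0 + timing$delivery + timing$tasting),
        duration = c(timing$cue, timing$delivery, timing$cue, timing$swallow),
        label = c("cue", lab, "cue", "swallow"),
        volume_ml = c(0, timing$volume_ml, 0, 0),
        stringsAsFactors = FALSE
      )
      t0 <- t0 + per_event
    }
  }
  events <- do.call(rbind, rows)
  events <- events[order(events$onset, events$label), , drop = FALSE]
  rownames(events) <- NULL

  total <- t0
  out <- list(
    events = events,
    tr = tr,
    n_volumes = as.integer(ceiling(total / tr)),
    total_duration = total,
    total_volume_ml = sum(events$volume_ml),
    timing = timing,
    sequences = sequences
  )
  class(out) <- "stim_schedule"
  out
}

#' @export
print.stim_schedule <- function(x, ...) {
  n_taste <- sum(x$events$label %in% taste_labels())
  cat(sprintf(
    "<stim_schedule> %d tastant events (+%d rinse), %.0f s total, TR %.3g s, %d volumes, %.0f ml\n",
    n_taste, sum(x$events$label == "water"), x$total_duration, x$tr,
    x$n_volumes, x$total_volume_ml))
  invisible(x)
}

# Event windows (onset, end) for one label class; tastes = delivery phase
# only, the modeled boxcar is assembled by the design-matrix builder.
schedule_events <- function(schedule, label) {
  ev <- schedule$events[schedule$events$label == label, , drop = FALSE]
  ev
}
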