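#' The Gaze Index: staring time over scanning time
#'
#' The Gaze Index (GI) is the ratio of time spent in long fixation
#' ("staring") to time spent in scanning motion, where scanning time is the
#' sum of saccade and microfixation time (a reading-like pattern is a chain
#' of saccades and sub-60 ms dwells). A GI of 0.11 means the participant
#' spent about nine times as much screen time scanning as staring. Because
#' it is a ratio of two portions of screen time, the GI is invariant to how
#' long the participant viewed the screen.
#'
#' @param events An [event_sequence()].
#' @return The dimensionless Gaze Index.
#' @export
gaze_index <- function(events) {
  stopifnot(inherits(events, "event_sequence"))
  ev <- events$events
  if (nrow(ev) == 0) stop("empty event sequence", call. = FALSE)
  stare <- sum(ev$duration_ms[ev$kind == "fixation"])
  scan <- sum(ev$duration_ms[ev$kind %in% c("saccade", "microfixation")])
  if (scan <= 0) {
    stop("Gaze Index undefined: no scanning (saccade + microfixation) time",
         call. = FALSE)
  }
  stare / scan
}

#' Categorize a Gaze Index value
#'
#' Participants with GI below 3 are "scanners", above 3 "starers"; the
#' extremes (GI below 1 and above 5) are "superscanners" and "superstarers".
#' A GI of exactly 3 is binned as starer (half-open bins; the tie has
#' measure zero).
#'
#' @param gi Positive Gaze Index value(s).
#' @return Character vector of categories.
#' @export
gi_category <- function(gi) {
  if (any(!is.finite(gi) | gi <= 0)) {
    stop("gi must be strictly positive", call. = FALSE)
  }
  out <- character(length(gi))
  out[gi < 1] <- "superscanner"
  out[gi >= 1 & gi < 3] <- "scanner"
  out[gi >= 3 & gi <= 5] <- "starer"
  out[gi > 5] <- "superstarer"
  out
}

#' Per-participant gaze metric suite
#'
#' Computes the participant-level summary of one classified recording:
#'
#' * `screen_time_fraction`: proportion of the task window spent in
#'   on-screen events (fixation + microfixation + saccade); off-screen
#'   episodes are excluded.
#' * `fixations_per_min`, `saccades_per_min`: event counts per minute of
#'   screen time.
#' * `mean_fixation_ms`, `mean_saccade_ms`: mean event durations.
#' * `mean_interfixation_px`: mean Euclidean distance between successive
#'   full-fixation centroids, skipping intervening microfixations and
#'   saccades; pairs separated by an off-screen episode are excluded because
#'   gaze re-acquisition makes the distance uninterpretable.
#' * `saccade_px_per_min`: summed saccade path length per minute of screen
#'   time. `saccade_px_per_saccade_min` is the alternative normalization per
#'   minute of saccadic movement, reported alongside.
#' * `gaze_index`, `gi_category`: see [gaze_index()] and [gi_category()].
#'
#' Rates are `NA` when screen time is zero; `mean_interfixation_px` is `NA`
#' with fewer than two usable fixation pairs; `gaze_index` is `NA` when
#' scanning time is zero.
#'
#' @param events An [event_sequence()].
#' @param stream The [gaze_stream()] the events were derived from; supplies
#'   the task duration. Alternatively give `task_duration_ms` directly.
#' @param task_duration_ms Task window used for `screen_time_fraction`.
#' @return A one-row data frame.
#' @export
compute_metrics <- function(events, stream = NULL, task_duration_ms = NULL) {
  stopifnot(inherits(events, "event_sequence"))
  ev <- events$events
  if (is.null(task_duration_ms)) {
    task_duration_ms <- if (!is.null(stream)) {
      stream$task_duration_ms
    } else if (nrow(ev)) {
      max(ev$end_ms)
    } else {
      NA_real_
    }
  }
  fix <- ev[ev$kind == "fixation", , drop = FALSE]
  mic <- ev[ev$kind == "microfixation", , drop = FALSE]
  sac <- ev[ev$kind == "saccade", , drop = FALSE]
  screen_ms <- sum(fix$duration_ms) + sum(mic$duration_ms) +
    sum(sac$duration_ms)
  screen_min <- screen_ms / 60000
  rate <- function(count) if (screen_ms > 0) count / screen_min else NA_real_

  # interfixation distances between consecutive fixations with no
  # intervening off-screen episode
  interfix <- NA_real_
  if (nrow(fix) >= 2) {
    idx <- which(ev$kind == "fixation")
    d <- numeric(0)
    for (j in seq_len(length(idx) - 1)) {
      between <- ev$kind[seq(idx[j] + 1L, idx[j + 1] - 1L)]
      if (!"offscreen" %in% between) {
        d <- c(d, sqrt((ev$centroid_x_px[idx[j + 1]] - ev$centroid_x_px[idx[j]])^2 +
                         (ev$centroid_y_px[idx[j + 1]] - ev$centroid_y_px[idx[j]])^2))
      }
    }
    if (length(d)) interfix <- mean(d)
  }

  gi <- tryCatch(gaze_index(events), error = function(e) NA_real_)
  data.frame(
    participant_id = events$participant_id,
    screen_time_fraction = if (is.na(task_duration_ms)) NA_real_ else screen_ms / task_duration_ms,
    fixations_per_min = rate(nrow(fix)),
    mean_fixation_ms = if (nrow(fix)) mean(fix$duration_ms) else NA_real_,
    mean_interfixation_px = interfix,
    saccade_px_per_min = if (screen_ms > 0) sum(sac$path_length_px) / screen_min else NA_real_,
    saccades_per_min = rate(nrow(sac)),
    mean_saccade_ms = if (nrow(sac)) mean(sac$duration_ms) else NA_real_,
    saccade_px_per_saccade_min = if (nrow(sac) && sum(sac$duration_ms) > 0) {
      sum(sac$path_length_px) / (sum(sac$duration_ms) / 60000)
    } else NA_real_,
    gaze_index = gi,
    gi_category = if (is.na(gi)) NA_character_ else gi_category(gi),
    stringsAsFactors = FALSE
  )
}
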