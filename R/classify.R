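#' Classifier parameters for velocity-threshold event detection
#'
#' The two thresholds of the I-VT rule: intervals with angular velocity
#' exceeding `velocity_threshold_deg_s` are saccadic; below-threshold runs
#' lasting more than `min_fixation_ms` are fixations, shorter ones are
#' microfixations.
#'
#' @param velocity_threshold_deg_s Saccade velocity threshold in degrees of
#'   visual angle per second (default 30).
#' @param min_fixation_ms Minimum fixation duration in milliseconds
#'   (default 60). The rule is strict: a run of exactly `min_fixation_ms` is
#'   a microfixation.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(velocity_threshold_deg_s = 30,
                              min_fixation_ms = 60) {
  if (!is.finite(velocity_threshold_deg_s) || velocity_threshold_deg_s <= 0 ||
      !is.finite(min_fixation_ms) || min_fixation_ms <= 0) {
    stop("classifier thresholds must be strictly positive", call. = FALSE)
  }
  structure(list(velocity_threshold_deg_s = velocity_threshold_deg_s,
                 min_fixation_ms = min_fixation_ms),
            class = "classifier_params")
}

event_kinds <- c("fixation", "microfixation", "saccade", "offscreen")

# Adjacent-kind legality: two low (stationary) kinds would have merged into
# one run; two adjacent saccade runs likewise.
illegal_adjacent <- function(a, b) {
  low <- c("fixation", "microfixation")
  (a == b) | (a %in% low & b %in% low)
}

#' Construct an event sequence
#'
#' An ordered, contiguous, non-overlapping list of gaze events covering the
#' span from the first to the last classified sample. Normally produced by
#' [classify_events()]; the constructor is exported so that event sequences
#' can also be built directly (e.g. for worked examples).
#'
#' @param participant_id Participant label.
#' @param events Data frame with columns `kind` (one of `"fixation"`,
#'   `"microfixation"`, `"saccade"`, `"offscreen"`), `start_ms`, `end_ms`,
#'   and optionally `centroid_x_px`, `centroid_y_px` (on-screen kinds) and
#'   `path_length_px` (saccades). `duration_ms` is derived.
#' @param validate Check ordering, contiguity and kind-alternation
#'   invariants (default `TRUE`).
#' @return An object of class `event_sequence`.
#' @export
event_sequence <- function(participant_id, events, validate = TRUE) {
  events <- as.data.frame(events)
  for (col in c("centroid_x_px", "centroid_y_px", "path_length_px")) {
    if (!col %in% names(events)) events[[col]] <- rep(NA_real_, nrow(events))
  }
  events$duration_ms <- events$end_ms - events$start_ms
  events <- events[c("kind", "start_ms", "end_ms", "duration_ms",
                     "centroid_x_px", "centroid_y_px", "path_length_px")]
  if (validate && nrow(events) > 0) {
    if (!all(events$kind %in% event_kinds)) {
      stop("unknown event kind", call. = FALSE)
    }
    if (any(events$duration_ms <= 0)) {
      stop("event durations must be strictly positive", call. = FALSE)
    }
    n <- nrow(events)
    if (n > 1) {
      if (any(abs(events$start_ms[-1] - events$end_ms[-n]) > 1e-6)) {
        stop("events must be contiguous", call. = FALSE)
      }
      if (any(illegal_adjacent(events$kind[-n], events$kind[-1]))) {
        stop("illegal adjacent event kinds (unmerged runs)", call. = FALSE)
      }
    }
  }
  structure(list(participant_id = as.character(participant_id),
                 events = events),
            class = "event_sequence")
}

#' @export
print.event_sequence <- function(x, ...) {
  tab <- table(factor(x$events$kind, levels = event_kinds))
  cat(sprintf("<event_sequence> participant %s: %d events (%s), span %.1f s\n",
              x$participant_id, nrow(x$events),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              if (nrow(x$events)) (max(x$events$end_ms) - min(x$events$start_ms)) / 1000 else 0))
  invisible(x)
}

#' @export
as.data.frame.event_sequence <- function(x, ...) {
  cbind(participant_id = x$participant_id, x$events)
}

#' Classify a gaze stream into fixations, microfixations, saccades and
#' off-screen episodes
#'
#' Velocity-threshold (I-VT) classification with a short-dwell extension:
#' each inter-sample interval is labelled off-screen if it touches an
#' invalid sample, saccadic if the two-point angular velocity exceeds the
#' threshold, and stationary otherwise. Maximal runs of equal labels become
#' events; stationary runs lasting more than `min_fixation_ms` are
#' fixations, shorter ones microfixations. The intervals adjacent to an
#' off-screen gap are absorbed into the off-screen event, and the stationary
#' runs on either side of a gap are evaluated against the fixation duration
#' rule independently.
#'
#' The result is deterministic, contiguous, and conserves time exactly: the
#' event durations sum to the span from the first to the last sample.
#'
#' @param stream A [gaze_stream()].
#' @param params A [classifier_params()].
#' @return An [event_sequence()].
#' @export
classify_events <- function(stream, params = classifier_params()) {
  stopifnot(inherits(stream, "gaze_stream"),
            inherits(params, "classifier_params"))
  s <- stream$samples
  n <- nrow(s)
  if (n < 2) stop("classification requires at least 2 samples", call. = FALSE)
  t <- s$t_ms
  valid <- s$valid & is.finite(s$x_px) & is.finite(s$y_px)
  if (sum(valid) < 2) {
    # everything is one off-screen episode
    ev <- data.frame(kind = "offscreen", start_ms = t[1], end_ms = t[n])
    return(event_sequence(stream$participant_id, ev))
  }
  x <- s$x_px
  y <- s$y_px
  dt <- diff(t)
  dx <- diff(x)
  dy <- diff(y)
  disp <- sqrt(dx^2 + dy^2)
  vel <- pixels_to_degrees(disp, stream$geometry) / (dt / 1000)
  off <- !valid[-n] | !valid[-1]
  lab <- integer(n - 1)            # 1 = stationary, 2 = saccade, 3 = offscreen
  lab[] <- 1L
  lab[!off & vel > params$velocity_threshold_deg_s] <- 2L
  lab[off] <- 3L

  runs <- rle(lab)
  ends <- cumsum(runs$lengths)          # interval index of run end
  starts <- ends - runs$lengths + 1L    # interval index of run start
  start_ms <- t[starts]
  end_ms <- t[ends + 1L]
  dur <- end_ms - start_ms

  kind <- character(length(runs$values))
  kind[runs$values == 2L] <- "saccade"
  kind[runs$values == 3L] <- "offscreen"
  low <- runs$values == 1L
  kind[low] <- ifelse(dur[low] > params$min_fixation_ms,
                      "fixation", "microfixation")

  # centroids over member samples (run samples starts..ends+1), via cumsums
  cx <- cumsum(c(0, ifelse(valid, x, 0)))
  cy <- cumsum(c(0, ifelse(valid, y, 0)))
  nsamp <- ends + 1L - starts + 1L
  cent_x <- (cx[ends + 2L] - cx[starts]) / nsamp
  cent_y <- (cy[ends + 2L] - cy[starts]) / nsamp
  cent_x[!low] <- NA_real_
  cent_y[!low] <- NA_real_

  cd <- cumsum(c(0, ifelse(is.na(disp), 0, disp)))
  path <- cd[ends + 1L] - cd[starts]
  path[runs$values != 2L] <- NA_real_

  ev <- data.frame(kind = kind, start_ms = start_ms, end_ms = end_ms,
                   centroid_x_px = cent_x, centroid_y_px = cent_y,
                   path_length_px = path)
  event_sequence(stream$participant_id, ev)
}

#' Export an event sequence as a tidy table
#'
#' @param events An [event_sequence()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_sequence"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
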