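#' Construct a gaze stream
#'
#' A gaze stream is the raw record of one participant's task: a sequence of
#' timestamped gaze samples together with the screen geometry they were
#' recorded on. Invalid samples (track loss, or the participant looking away
#' from the screen, e.g. at written notes) are retained with `valid = FALSE`
#' rather than dropped, because off-screen time is itself an analyzed
#' quantity.
#'
#' @param participant_id Opaque participant label.
#' @param samples Data frame with columns `t_ms` (milliseconds from task
#'   start), `x_px`, `y_px` (pixel coordinates, may be `NA` when invalid) and
#'   `valid` (logical).
#' @param geometry A [screen_geometry()].
#' @param nominal_rate_hz Nominal sampling rate. Informational only: all
#'   downstream computation uses actual timestamps.
#' @param task_duration_ms Task window length; defaults to the 10-minute
#'   task (600000 ms), or to the last timestamp if that is later.
#' @return An object of class `gaze_stream`.
#' @export
gaze_stream <- function(participant_id, samples, geometry,
                        nominal_rate_hz = 30, task_duration_ms = 600000) {
  stopifnot(inherits(geometry, "screen_geometry"))
  req <- c("t_ms", "x_px", "y_px", "valid")
  if (!all(req %in% names(samples))) {
    stop("samples must have columns t_ms, x_px, y_px, valid", call. = FALSE)
  }
  samples <- as.data.frame(samples)[req]
  samples$valid <- as.logical(samples$valid)
  n <- nrow(samples)
  if (n > 0) {
    if (any(!is.finite(samples$t_ms)) || samples$t_ms[1] < 0) {
      stop("timestamps must be finite and nonnegative", call. = FALSE)
    }
    if (n > 1 && any(diff(samples$t_ms) <= 0)) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
    v <- samples$valid
    bad <- v & (!is.finite(samples$x_px) | !is.finite(samples$y_px) |
                  samples$x_px < 0 | samples$x_px >= geometry$width_px |
                  samples$y_px < 0 | samples$y_px >= geometry$height_px)
    if (any(bad)) {
      stop("valid samples must have coordinates inside screen bounds",
           call. = FALSE)
    }
    task_duration_ms <- max(task_duration_ms, samples$t_ms[n])
  }
  structure(list(participant_id = as.character(participant_id),
                 samples = samples, geometry = geometry,
                 nominal_rate_hz = nominal_rate_hz,
                 task_duration_ms = task_duration_ms),
            class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<gaze_stream> participant %s: %d samples, %.1f s span, %.0f%% valid\n",
              x$participant_id, n,
              if (n > 1) diff(range(x$samples$t_ms)) / 1000 else 0,
              if (n > 0) 100 * mean(x$samples$valid) else NA_real_))
  invisible(x)
}

# Sniff the field delimiter of a delimited text file from its header line.
detect_delimiter <- function(header) {
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a gaze stream from delimited text
#'
#' Reads a CSV or TSV export (delimiter auto-detected from the header) with
#' columns `t_ms`, `x_px`, `y_px` and optionally `valid`. Samples are sorted
#' by timestamp and exact duplicate timestamps are dropped (first occurrence
#' kept). When the validity column is absent, validity is inferred from the
#' coordinates lying inside the screen bounds.
#'
#' @param path File to read.
#' @param geometry A [screen_geometry()].
#' @param nominal_rate_hz Nominal sampling rate to record on the stream.
#' @param participant_id Participant label; defaults to the file name.
#' @param task_duration_ms Task window; see [gaze_stream()].
#' @return A [gaze_stream()].
#' @export
read_gaze_stream <- function(path, geometry, nominal_rate_hz = 30,
                             participant_id = NULL,
                             task_duration_ms = 600000) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty gaze file: ", path, call. = FALSE)
  sep <- detect_delimiter(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(df) == 0) stop("gaze file has no samples: ", path, call. = FALSE)
  req <- c("t_ms", "x_px", "y_px")
  if (!all(req %in% names(df))) {
    stop("gaze file must have header columns t_ms, x_px, y_px", call. = FALSE)
  }
  df <- df[order(df$t_ms), , drop = FALSE]
  df <- df[!duplicated(df$t_ms), , drop = FALSE]
  if (nrow(df) > 1 && any(diff(df$t_ms) <= 0)) {
    stop("non-monotonic timestamps after de-duplication", call. = FALSE)
  }
  xy <- c(df$x_px, df$y_px)
  lim <- c(-geometry$width_px, 2 * geometry$width_px)
  if (any(xy < lim[1] | xy > lim[2], na.rm = TRUE)) {
    stop("coordinates far outside the screen band: corrupt export",
         call. = FALSE)
  }
  if (!"valid" %in% names(df)) {
    df$valid <- is.finite(df$x_px) & is.finite(df$y_px) &
      df$x_px >= 0 & df$x_px < geometry$width_px &
      df$y_px >= 0 & df$y_px < geometry$height_px
  } else {
    df$valid <- as.logical(df$valid)
    df$valid[is.na(df$valid)] <- FALSE
  }
  # samples flagged valid but with out-of-bounds coordinates are demoted
  oob <- df$valid & (!is.finite(df$x_px) | !is.finite(df$y_px) |
                       df$x_px < 0 | df$x_px >= geometry$width_px |
                       df$y_px < 0 | df$y_px >= geometry$height_px)
  df$valid[oob] <- FALSE
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  gaze_stream(participant_id, df[c("t_ms", "x_px", "y_px", "valid")],
              geometry, nominal_rate_hz, task_duration_ms)
}

# Format doubles so that read.table recovers them bit-identically.
format_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  trimws(out)
}

#' Write a gaze stream to delimited text
#'
#' Writes `t_ms,x_px,y_px,valid` rows with full double precision, so that
#' [read_gaze_stream()] recovers the sample values exactly.
#'
#' @param stream A [gaze_stream()].
#' @param path Destination file.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_gaze_stream <- function(stream, path, sep = ",") {
  stopifnot(inherits(stream, "gaze_stream"))
  s <- stream$samples
  lines <- paste(format_full(s$t_ms), format_full(s$x_px),
                 format_full(s$y_px), s$valid, sep = sep)
  writeLines(c(paste(c("t_ms", "x_px", "y_px", "valid"), collapse = sep),
               lines), path)
  invisible(path)
}

#' Cohort metadata records
#'
#' One row per participant: the sex label used for the group comparison, an
#' optional specialty label, and an optional task-performance covariate (the
#' percentage of embedded safety items the participant identified).
#'
#' @param participant_id Character vector of participant labels.
#' @param sex_label `"female"` or `"male"` per participant.
#' @param specialty Optional specialty labels.
#' @param performance_pct Optional performance percentages in `[0, 100]`.
#' @return A data frame of class `cohort_records`.
#' @export
cohort_records <- function(participant_id, sex_label, specialty = NA_character_,
                           performance_pct = NA_real_) {
  sex_label <- as.character(sex_label)
  if (!all(sex_label %in% c("female", "male"))) {
    stop("sex_label must be 'female' or 'male'", call. = FALSE)
  }
  if (any(performance_pct < 0 | performance_pct > 100, na.rm = TRUE)) {
    stop("performance_pct must lie in [0, 100]", call. = FALSE)
  }
  out <- data.frame(participant_id = as.character(participant_id),
                    sex_label = sex_label,
                    specialty = specialty,
                    performance_pct = performance_pct,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_records", "data.frame")
  out
}

#' Write a tidy results table
#'
#' Writes per-participant metric rows or group-comparison rows as a CSV with
#' a stable, documented column order (the column order of the input). The
#' rows must be of one homogeneous kind.
#'
#' @param rows A data frame from [compute_metrics()] (possibly row-bound) or
#'   from [compare_cohort()], or a list of such one-kind data frames.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    kinds <- vapply(rows, function(r) paste(sort(names(r)), collapse = "|"),
                    character(1))
    if (length(unique(kinds)) > 1) {
      stop("mixed row kinds: all rows must share the same columns",
           call. = FALSE)
    }
    rows <- do.call(rbind, rows)
  }
  stopifnot(is.data.frame(rows))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path File to read.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read/write a flat key-value configuration file
#'
#' The configuration dialect is one `key = value` pair per line; blank lines
#' and `#` comments are ignored. Used for screen geometry plus classifier
#' thresholds.
#'
#' @param path File to read or write.
#' @return `read_config()`: a named list (numeric where possible).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  vals <- lapply(kv, function(p) {
    num <- suppressWarnings(as.numeric(p[2]))
    if (is.na(num)) p[2] else num
  })
  stats::setNames(vals, vapply(kv, `[`, character(1), 1))
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(lapply(config, format_full)),
                   sep = " = "), path)
  invisible(path)
}

#' Geometry from a configuration list
#'
#' @param config Named list with the five screen-geometry fields (e.g. from
#'   [read_config()]).
#' @return A [screen_geometry()].
#' @export
geometry_from_config <- function(config) {
  screen_geometry(width_px = config$width_px, height_px = config$height_px,
                  width_cm = config$width_cm, height_cm = config$height_cm,
                  viewing_distance_cm = config$viewing_distance_cm)
}
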