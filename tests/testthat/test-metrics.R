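gi_seq <- function(fix_ms, sacc_ms, micro_ms = 0) {
  ev <- data.frame(kind = c("fixation", "saccade"),
                   start_ms = c(0, fix_ms),
                   end_ms = c(fix_ms, fix_ms + sacc_ms))
  if (micro_ms > 0) {
    ev <- rbind(ev, data.frame(kind = "microfixation",
                               start_ms = fix_ms + sacc_ms,
                               end_ms = fix_ms + sacc_ms + micro_ms))
  }
  event_sequence("p", ev, validate = FALSE)
}

test_that("Gaze Index is stare time over scan time", {
  # equal stare and scan -> 1
  expect_equal(gaze_index(gi_seq(1000, 1000)), 1)
  # 300 s fixation, 75 s saccade, 25 s microfixation -> 3.0
  expect_equal(gaze_index(gi_seq(300000, 75000, 25000)), 3)
  # microfixation time counts toward scanning, not staring
  expect_equal(gaze_index(gi_seq(1000, 500, 500)), 1)
  # scanning nine times the staring -> 1/9, printed as 0.11
  expect_equal(gaze_index(gi_seq(6000, 53950, 50)), 1 / 9)
  expect_equal(round(gaze_index(gi_seq(6000, 53950, 50)), 2), 0.11)
})

test_that("Gaze Index error cases and invariants", {
  expect_error(gaze_index(event_sequence("p", data.frame(
    kind = character(0), start_ms = numeric(0), end_ms = numeric(0)))),
    "empty")
  only_fix <- event_sequence("p", data.frame(kind = "fixation",
                                             start_ms = 0, end_ms = 100))
  expect_error(gaze_index(only_fix), "undefined")
  # gi * scan time = stare time, exactly; concatenation leaves gi unchanged
  for (seed in c(5, 9)) {
    st <- random_stream(seed)
    ev <- classify_events(st)
    gi <- tryCatch(gaze_index(ev), error = function(e) NULL)
    if (is.null(gi)) next
    e <- ev$events
    stare <- sum(e$duration_ms[e$kind == "fixation"])
    scan <- sum(e$duration_ms[e$kind %in% c("saccade", "microfixation")])
    expect_equal(gi * scan, stare)
    doubled <- event_sequence("p", rbind(
      e, transform(e, start_ms = start_ms + max(e$end_ms),
                   end_ms = end_ms + max(e$end_ms))), validate = FALSE)
    expect_equal(gaze_index(doubled), gi)
  }
})

test_that("GI categories follow the half-open binning rule", {
  expect_equal(gi_category(0.11), "superscanner")
  expect_equal(gi_category(7.02), "superstarer")
  expect_equal(gi_category(c(0.999, 1, 2.9, 3, 5, 5.001)),
               c("superscanner", "scanner", "scanner", "starer", "starer",
                 "superstarer"))
  expect_error(gi_category(0), "positive")
})

test_that("metric suite arithmetic on a hand-built sequence", {
  ev <- data.frame(
    kind = c("fixation", "saccade", "fixation"),
    start_ms = c(0, 100, 150),
    end_ms = c(100, 150, 250),
    centroid_x_px = c(0, NA, 300),
    centroid_y_px = c(0, NA, 400),
    path_length_px = c(NA, 500, NA))
  es <- event_sequence("p", ev)
  m <- compute_metrics(es, task_duration_ms = 600000)
  expect_equal(m$mean_fixation_ms, 100)
  expect_equal(m$mean_interfixation_px, 500)   # 3-4-5 triangle
  expect_equal(m$screen_time_fraction, 250 / 600000)
  expect_equal(m$saccade_px_per_min, 500 / (250 / 60000))
  expect_equal(m$saccades_per_min, 1 / (250 / 60000))
  expect_equal(m$mean_saccade_ms, 50)
  expect_equal(m$gaze_index, 200 / 50)
  expect_equal(m$gi_category, "starer")
  # the alternative normalization: per minute of saccadic movement
  expect_equal(m$saccade_px_per_saccade_min, 500 / (50 / 60000))
})

test_that("degenerate sequences flag rates as undefined", {
  off <- event_sequence("p", data.frame(kind = "offscreen", start_ms = 0,
                                        end_ms = 5000))
  m <- compute_metrics(off, task_duration_ms = 600000)
  expect_equal(m$screen_time_fraction, 0)
  expect_true(is.na(m$fixations_per_min))
  expect_true(is.na(m$gaze_index))
  # fewer than two fixations -> interfixation distance undefined
  one_fix <- event_sequence("p", data.frame(
    kind = c("fixation", "saccade"), start_ms = c(0, 100),
    end_ms = c(100, 150), centroid_x_px = c(5, NA),
    centroid_y_px = c(5, NA), path_length_px = c(NA, 60)))
  expect_true(is.na(compute_metrics(one_fix,
                                    task_duration_ms = 1000)$mean_interfixation_px))
})

test_that("interfixation pairs spanning an off-screen gap are excluded", {
  ev <- data.frame(
    kind = c("fixation", "saccade", "fixation", "offscreen", "fixation"),
    start_ms = c(0, 100, 150, 250, 5250),
    end_ms = c(100, 150, 250, 5250, 5350),
    centroid_x_px = c(0, NA, 30, NA, 1000),
    centroid_y_px = c(0, NA, 40, NA, 1000),
    path_length_px = c(NA, 100, NA, NA, NA))
  m <- compute_metrics(event_sequence("p", ev), task_duration_ms = 600000)
  expect_equal(m$mean_interfixation_px, 50)   # only the pre-gap pair
})

test_that("doubling every duration preserves the scale-free metrics", {
  st <- generate_stream(default_profiles()$female, seed = 6,
                        task_duration_ms = 60000)
  ev <- classify_events(st)
  m1 <- compute_metrics(ev, st)
  e2 <- ev$events
  e2$start_ms <- e2$start_ms * 2
  e2$end_ms <- e2$end_ms * 2
  m2 <- compute_metrics(event_sequence("p", e2, validate = FALSE),
                        task_duration_ms = 2 * st$task_duration_ms)
  expect_equal(m2$gaze_index, m1$gaze_index)
  expect_equal(m2$screen_time_fraction, m1$screen_time_fraction)
  expect_equal(m2$saccades_per_min / m2$fixations_per_min,
               m1$saccades_per_min / m1$fixations_per_min)
})
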