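test_that("default profiles satisfy their calibration identities", {
  pr <- default_profiles()
  expect_equal(pr$female$gi_mean, 2.4)
  expect_equal(pr$male$onscreen_fraction, 0.551)
  for (sex in c("female", "male")) {
    p <- pr[[sex]]
    expect_gt(p$saccade_speed_deg_s, 30)
    expect_lt(p$microfix_ms_mean, 60)
    expect_gt(p$fixation_ms_mean, 60)
    e <- profile_expectations(p)
    # analytic cohort expectations reproduce the calibration targets
    expect_equal(e$mean_fixation_ms, p$fixation_ms_mean, tolerance = 0.01)
    expect_equal(e$mean_saccade_ms, p$saccade_ms_mean, tolerance = 0.01)
    expect_equal(e$saccades_per_min, p$saccade_rate_per_min,
                 tolerance = 0.015)
    expect_equal(e$saccade_px_per_min, p$saccade_px_per_min,
                 tolerance = 0.015)
    expect_equal(e$gaze_index, p$gi_mean, tolerance = 0.02)
    expect_equal(e$screen_time_fraction, p$onscreen_fraction,
                 tolerance = 0.01)
  }
})

test_that("profile invariants are enforced", {
  expect_error(behavior_profile("x", fixation_ms_mean = 50,
                                saccade_ms_mean = 60,
                                scan_bout_fraction = 0.3,
                                onscreen_fraction = 0.5),
               "exceed 60")
  expect_error(behavior_profile("x", fixation_ms_mean = 200,
                                saccade_ms_mean = 60,
                                saccade_speed_deg_s = 20,
                                scan_bout_fraction = 0.3,
                                onscreen_fraction = 0.5),
               "threshold")
  expect_error(behavior_profile("x", fixation_ms_mean = 200,
                                saccade_ms_mean = 60,
                                scan_bout_fraction = 1.2,
                                onscreen_fraction = 0.5),
               "fractions")
})

test_that("identical seeds give bit-identical streams; seeds derive per participant", {
  pr <- default_profiles()
  a <- generate_stream(pr$male, seed = 5, task_duration_ms = 30000)
  b <- generate_stream(pr$male, seed = 5, task_duration_ms = 30000)
  expect_identical(a$samples, b$samples)
  d <- generate_stream(pr$male, seed = 6, task_duration_ms = 30000)
  expect_false(identical(a$samples, d$samples))
  s1 <- generate_cohort(small_cohort_spec(seed = 9, n = 2, task_ms = 30000))
  s2 <- generate_cohort(small_cohort_spec(seed = 9, n = 2, task_ms = 30000))
  expect_identical(s1$streams[[3]]$samples, s2$streams[[3]]$samples)
})

test_that("a stream has the expected sample count and grid", {
  st <- generate_stream(default_profiles()$female, seed = 2)
  expect_equal(nrow(st$samples), 18001)
  expect_equal(st$samples$t_ms[1], 0)
  expect_equal(max(st$samples$t_ms), 600000, tolerance = 1e-6)
  expect_lte(max(st$samples$t_ms), st$task_duration_ms)
})

test_that("generated saccade steps exceed the threshold and jitter never does", {
  pr <- default_profiles()
  thr_px <- px_at_threshold(1000 / 30)
  n_checked <- 0
  for (seed in 1:6) {
    st <- generate_stream(if (seed %% 2) pr$female else pr$male, seed = seed,
                          task_duration_ms = 150000)
    s <- st$samples
    d <- sqrt(diff(s$x_px)^2 + diff(s$y_px)^2)
    ev <- classify_events(st)$events
    # every on-screen inter-sample displacement is cleanly on one side
    on <- !is.na(d)
    expect_true(all(d[on] < thr_px * 0.999 | d[on] > thr_px * 1.001))
    n_checked <- n_checked + sum(on)
  }
  expect_gt(n_checked, 10000)
})

test_that("scan fraction near zero yields almost pure staring", {
  p <- behavior_profile("starer_limit", fixation_ms_mean = 400,
                        saccade_ms_mean = 60, scan_bout_fraction = 0.005,
                        onscreen_fraction = 0.9,
                        saccade_speed_deg_s = 100)
  st <- generate_stream(p, seed = 3, task_duration_ms = 120000)
  ev <- classify_events(st)$events
  on <- ev$kind != "offscreen"
  fix_share <- sum(ev$duration_ms[ev$kind == "fixation"]) /
    sum(ev$duration_ms[on])
  expect_gte(fix_share, 0.99)
})

test_that("cv = 0 collapses heterogeneity; swapping profiles swaps differences", {
  spec <- small_cohort_spec(seed = 3, n = 4)
  spec$between_participant_cv <- 0
  sim <- generate_cohort(spec)
  par <- sim$participants
  for (col in c("scan_fraction", "fixation_ms", "saccade_ms")) {
    expect_equal(length(unique(par[[col]][par$sex_label == "female"])), 1)
  }
  pr <- default_profiles()
  swapped <- cohort_spec(n_female = 8, n_male = 8, seed = 11,
                         task_duration_ms = 120000,
                         profiles = list(female = pr$male, male = pr$female))
  normal <- cohort_spec(n_female = 8, n_male = 8, seed = 11,
                        task_duration_ms = 120000)
  gm <- function(spec) {
    sim <- generate_cohort(spec)
    mets <- do.call(rbind, lapply(sim$streams, function(st) {
      compute_metrics(classify_events(st), st)
    }))
    f <- sim$cohort$sex_label == "female"
    mean(mets$mean_fixation_ms[f]) - mean(mets$mean_fixation_ms[!f])
  }
  expect_lt(gm(normal), 0)     # females have shorter fixations
  expect_gt(gm(swapped), 0)
})

test_that("classified streams recover per-participant parameters", {
  # long homogeneous runs: classified means approach the profile values
  pr <- default_profiles()
  p <- behavior_profile("check", fixation_ms_mean = 220,
                        saccade_ms_mean = 60, scan_bout_fraction = 0.35,
                        onscreen_fraction = 0.6,
                        saccade_speed_deg_s = 60)
  mets <- do.call(rbind, lapply(1:4, function(s) {
    st <- generate_stream(p, seed = s, task_duration_ms = 300000)
    compute_metrics(classify_events(st), st)
  }))
  expect_equal(mean(mets$mean_fixation_ms), 220, tolerance = 0.03)
  expect_equal(mean(mets$mean_saccade_ms), 60, tolerance = 0.03)
  expect_equal(mean(mets$screen_time_fraction), 0.6, tolerance = 0.05)
  # scan fraction: gi = (1-c)/c
  expect_equal(mean(mets$gaze_index), 0.65 / 0.35, tolerance = 0.05)
})
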