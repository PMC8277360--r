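# Shared fixtures and independent reference implementations.

default_geom <- screen_geometry()

# Pixel displacement corresponding to 30 deg/s over dt_ms at the default
# geometry (used to construct supra/sub-threshold steps in fixtures).
px_at_threshold <- function(dt_ms, geom = default_geom,
                            deg_s = 30) {
  degrees_to_pixels(deg_s * dt_ms / 1000, geom)
}

# Build a gaze stream from plain vectors.
make_stream <- function(t, x, y, valid = NULL, geom = default_geom,
                        id = "p1", task_ms = NULL) {
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  if (is.null(task_ms)) task_ms <- max(t)
  gaze_stream(id, data.frame(t_ms = t, x_px = x, y_px = y, valid = valid),
              geom, task_duration_ms = task_ms)
}

# Stream that dwells at a point for n samples at a given rate.
constant_stream <- function(n, dt = 1000 / 30, x0 = 400, y0 = 300,
                            geom = default_geom) {
  t <- (0:(n - 1)) * dt
  make_stream(t, rep(x0, n), rep(y0, n), geom = geom)
}

# Independent brute-force classifier: label every inter-sample interval on
# its own, then merge maximal runs and apply the 60 ms rule. Written as a
# literal loop, deliberately separate from the vectorized implementation.
oracle_classify <- function(stream, params = classifier_params()) {
  s <- stream$samples
  n <- nrow(s)
  t <- s$t_ms; x <- s$x_px; y <- s$y_px
  ok <- s$valid & is.finite(x) & is.finite(y)
  lab <- character(n - 1)
  for (i in seq_len(n - 1)) {
    if (!ok[i] || !ok[i + 1]) {
      lab[i] <- "off"
    } else {
      v <- angular_velocity(list(t_ms = t[i], x_px = x[i], y_px = y[i],
                                 valid = TRUE),
                            list(t_ms = t[i + 1], x_px = x[i + 1],
                                 y_px = y[i + 1], valid = TRUE),
                            stream$geometry)
      lab[i] <- if (v > params$velocity_threshold_deg_s) "sacc" else "low"
    }
  }
  kinds <- character(0); t0s <- numeric(0); t1s <- numeric(0)
  start <- 1L
  for (i in seq_len(n - 1)) {
    if (i == n - 1 || lab[i + 1] != lab[i]) {
      t0 <- t[start]; t1 <- t[i + 1]
      kind <- switch(lab[i],
                     off = "offscreen",
                     sacc = "saccade",
                     low = if (t1 - t0 > params$min_fixation_ms) "fixation"
                           else "microfixation")
      kinds <- c(kinds, kind); t0s <- c(t0s, t0); t1s <- c(t1s, t1)
      start <- i + 1L
    }
  }
  data.frame(kind = kinds, start_ms = t0s, end_ms = t1s)
}

# Randomized gaze stream with dwell segments, jumps and track-loss gaps;
# irregular sampling to exercise the timestamp-driven logic.
random_stream <- function(seed, n_max = 200, geom = default_geom) {
  set.seed(seed)
  n <- sample(5:n_max, 1)
  dt <- runif(n - 1, 20, 50)
  t <- c(0, cumsum(dt))
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 100, geom$width_px - 100)
  y[1] <- runif(1, 100, geom$height_px - 100)
  for (i in 2:n) {
    if (runif(1) < 0.25) {             # jump (likely supra-threshold)
      step <- runif(1, 30, 400)
      th <- runif(1, 0, 2 * pi)
      x[i] <- x[i - 1] + step * cos(th)
      y[i] <- y[i - 1] + step * sin(th)
    } else {                           # dwell drift
      x[i] <- x[i - 1] + rnorm(1, 0, 4)
      y[i] <- y[i - 1] + rnorm(1, 0, 4)
    }
    x[i] <- min(max(x[i], 0), geom$width_px - 1)
    y[i] <- min(max(y[i], 0), geom$height_px - 1)
  }
  valid <- runif(n) > 0.12
  # occasional longer gaps
  if (runif(1) < 0.5) {
    g0 <- sample(n, 1); valid[g0:min(n, g0 + sample(1:5, 1))] <- FALSE
  }
  x[!valid] <- NA; y[!valid] <- NA
  make_stream(t, x, y, valid, geom = geom)
}

# Full-enumeration Mann-Whitney oracle (tie-free inputs): exact two-sided
# p as the null probability of a min-U at most as large as observed.
mw_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- min(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2,
               n1 * n2 - (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2))
  combs <- utils::combn(n1 + n2, n1)
  stats <- apply(combs, 2, function(idx) {
    u1 <- sum(r[idx]) - n1 * (n1 + 1) / 2
    min(u1, n1 * n2 - u1)
  })
  list(u = u_obs, p = mean(stats <= u_obs))
}

# Dwell - jump - dwell stream: two fixations joined by one saccade.
make_jump_stream <- function(dt = 1000 / 30, n_dwell = 8,
                             geom = default_geom) {
  n <- 2 * n_dwell + 1
  t <- (0:(n - 1)) * dt
  x <- c(rep(200, n_dwell), 400, rep(600, n_dwell))
  y <- c(rep(200, n_dwell), 350, rep(500, n_dwell))
  make_stream(t, x, y, geom = geom)
}

# Small calibrated cohort for fast end-to-end tests.
small_cohort_spec <- function(seed = 1, n = 6, task_ms = 120000) {
  cohort_spec(n_female = n, n_male = n, seed = seed,
              task_duration_ms = task_ms)
}
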