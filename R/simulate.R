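#' Behavioral profile for the synthetic gaze-stream generator
#'
#' A behavioral profile describes one stare/scan phenotype as the generator's
#' parameters: how long fixations last, how fast and how often saccades
#' occur, how on-screen time is split between stare bouts and reading-like
#' scan bouts (saccade-microfixation chains), and how much of the task is
#' spent off screen (looks at paper notes).
#'
#' Cohort-level profiles built by [default_profiles()] additionally carry
#' calibrated between-participant heterogeneity: the per-participant scan
#' fraction follows a Beta distribution (`scan_alpha`, `scan_beta`) and the
#' per-participant duration means follow mean-preserving lognormal spreads,
#' with high Gaze Index participants receiving proportionally longer
#' fixations (`fix_elev_kappa` times their GI times their saccade duration,
#' the structural minimum that event alternation imposes).
#'
#' @param label Profile label.
#' @param fixation_ms_mean Mean full-fixation duration (ms), must exceed
#'   60 ms.
#' @param fixation_ms_shape Gamma shape of fixation durations (default 4).
#' @param fixation_ms_sd Between-participant SD of per-participant mean
#'   fixation duration (0 = homogeneous).
#' @param saccade_ms_mean,saccade_ms_shape,saccade_ms_sd Saccade duration
#'   distribution: mean (ms), gamma shape (default 3), between-participant
#'   SD of the mean.
#' @param saccade_rate_per_min Expected saccades per minute of screen time.
#' @param microfix_ms_mean Microfixation dwell duration (ms), below 60. At a
#'   given sampling rate a microfixation is a single inter-sample interval,
#'   so this equals the sample period.
#' @param saccade_speed_deg_s Within-saccade angular speed, above the 30
#'   deg/s threshold (default 100).
#' @param scan_bout_fraction Mean fraction of on-screen time in scan bouts.
#' @param onscreen_fraction Target fraction of task time spent on screen.
#' @param offscreen_bout_ms_mean Mean off-screen episode duration (ms).
#' @param onscreen_bout_ms_mean Mean on-screen episode duration (ms);
#'   derived from `onscreen_fraction` and the off-screen mean when `NULL`.
#' @param onscreen_bout_cv Between-participant CV of the on-screen episode
#'   mean.
#' @param gi_mean Target cohort mean Gaze Index.
#' @param heterogeneity `NULL` (homogeneous cohort: every participant at the
#'   profile means) or the between-participant model solved by
#'   [default_profiles()]: a list with the truncated-lognormal Gaze Index
#'   distribution (`gi_mu`, `gi_sigma`, `gi_lo`, `gi_hi`), the
#'   saccade-duration coupling (`rho_s`, `smult_norm`, `sig_s`, `s_scale`),
#'   the fixation-duration base (`fix_base_mean`, `fix_base_sigma`,
#'   `kappa`) and the on-screen bout spread (`sig_t`).
#' @param saccade_px_per_min Target saccade path length per minute of screen
#'   time (informational; realized through `saccade_speed_deg_s`).
#' @param performance_mean,performance_sd Task-performance covariate
#'   distribution (percent of safety items identified).
#' @param nominal_rate_hz Sampling rate the calibrated parameters assume.
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(label,
                             fixation_ms_mean,
                             fixation_ms_shape = 4,
                             fixation_ms_sd = 0,
                             saccade_ms_mean,
                             saccade_ms_shape = 3,
                             saccade_ms_sd = 0,
                             saccade_rate_per_min = NA_real_,
                             microfix_ms_mean = 1000 / 30,
                             saccade_speed_deg_s = 100,
                             scan_bout_fraction,
                             onscreen_fraction,
                             offscreen_bout_ms_mean = 5000,
                             onscreen_bout_ms_mean = NULL,
                             onscreen_bout_cv = 0,
                             gi_mean = NA_real_,
                             heterogeneity = NULL,
                             saccade_px_per_min = NA_real_,
                             performance_mean = NA_real_,
                             performance_sd = NA_real_,
                             nominal_rate_hz = 30) {
  if (!is.finite(fixation_ms_mean) || fixation_ms_mean <= 60) {
    stop("fixation_ms_mean must exceed 60 ms", call. = FALSE)
  }
  if (!is.finite(microfix_ms_mean) || microfix_ms_mean >= 60 ||
      microfix_ms_mean <= 0) {
    stop("microfix_ms_mean must lie in (0, 60) ms", call. = FALSE)
  }
  if (!is.finite(saccade_speed_deg_s) || saccade_speed_deg_s <= 30) {
    stop("saccade_speed_deg_s must exceed the 30 deg/s threshold",
         call. = FALSE)
  }
  for (fr in c(scan_bout_fraction, onscreen_fraction)) {
    if (!is.finite(fr) || fr <= 0 || fr >= 1) {
      stop("fractions must lie strictly inside (0, 1)", call. = FALSE)
    }
  }
  if (saccade_ms_mean <= 0) stop("saccade_ms_mean must be positive",
                                 call. = FALSE)
  if (is.null(onscreen_bout_ms_mean)) {
    onscreen_bout_ms_mean <- offscreen_bout_ms_mean * onscreen_fraction /
      (1 - onscreen_fraction)
  }
  structure(list(label = label,
                 fixation_ms_mean = fixation_ms_mean,
                 fixation_ms_shape = fixation_ms_shape,
                 fixation_ms_sd = fixation_ms_sd,
                 saccade_ms_mean = saccade_ms_mean,
                 saccade_ms_shape = saccade_ms_shape,
                 saccade_ms_sd = saccade_ms_sd,
                 saccade_rate_per_min = saccade_rate_per_min,
                 microfix_ms_mean = microfix_ms_mean,
                 saccade_speed_deg_s = saccade_speed_deg_s,
                 scan_bout_fraction = scan_bout_fraction,
                 onscreen_fraction = onscreen_fraction,
                 offscreen_bout_ms_mean = offscreen_bout_ms_mean,
                 onscreen_bout_ms_mean = onscreen_bout_ms_mean,
                 onscreen_bout_cv = onscreen_bout_cv,
                 gi_mean = gi_mean,
                 heterogeneity = heterogeneity,
                 saccade_px_per_min = saccade_px_per_min,
                 performance_mean = performance_mean,
                 performance_sd = performance_sd,
                 nominal_rate_hz = nominal_rate_hz),
            class = "behavior_profile")
}

#' @export
print.behavior_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<behavior_profile> %s: fixation %.1f ms, saccade %.1f ms at %.0f/min,",
    " scan fraction %.3f, on-screen %.3f, GI %.2f\n"),
    x$label, x$fixation_ms_mean, x$saccade_ms_mean, x$saccade_rate_per_min,
    x$scan_bout_fraction, x$onscreen_fraction, x$gi_mean))
  invisible(x)
}

# --- calibration ------------------------------------------------------------

# Expectation of max(m0, round(G / delta)) for G ~ gamma(shape, mean mu):
# the mean number of sample intervals a duration drawn from the gamma
# occupies after grid discretization with a floor of m0 intervals.
disc_gamma_mean <- function(mu, shape, delta, m0) {
  rt <- shape / mu
  nmax <- max(m0 + 2, ceiling((mu + 14 * mu / sqrt(shape)) / delta))
  n <- m0:nmax
  Fn <- stats::pgamma((n + 0.5) * delta, shape, rt)
  p <- diff(c(0, Fn))
  sum(n * p) + (1 - Fn[length(Fn)]) * (nmax + 1)
}

# Solve for the continuous gamma mean whose discretized expectation matches
# target_ms on the delta grid (floor m0 intervals).
solve_disc_mu <- function(target_ms, shape, delta, m0) {
  target_n <- target_ms / delta
  if (target_n <= m0 + 1e-9) return(NA_real_)  # degenerate: always m0
  stats::uniroot(function(mu) disc_gamma_mean(mu, shape, delta, m0) - target_n,
                 interval = c(delta / 10, target_ms * 3),
                 tol = 1e-7, extendInt = "upX")$root
}

# Inverse CDF of the bounded power-law (log-tilted) distribution with
# density proportional to x^(lambda - 1) on [lo, hi]; lambda = 0 is the
# log-uniform case.
qpowlaw <- function(u, lambda, lo, hi) {
  if (abs(lambda) < 1e-8) {
    exp(log(lo) + u * (log(hi) - log(lo)))
  } else {
    (lo^lambda + u * (hi^lambda - lo^lambda))^(1 / lambda)
  }
}

# Evaluate the between-participant heterogeneity model on given deviates.
# Single source of truth for both the calibration Monte Carlo and cohort
# draws. Returns per-participant generator parameters.
# Quantile function of the two-phenotype Gaze Index mixture: with
# probability w a "scanner" draw (power-law on [lo, split]), otherwise a
# "starer" draw (uniform on [split, hi]).
qgi_mixture <- function(u, w, lambda, lo, split, hi) {
  scan <- u < w
  out <- numeric(length(u))
  out[scan] <- qpowlaw(u[scan] / w, lambda, lo, split)
  out[!scan] <- qpowlaw((u[!scan] - w) / (1 - w), 1, split, hi)
  out
}

hetero_eval <- function(h, s_t, delta, t_on, U, Zf, Zs, Zt, scale = 1) {
  if (scale <= 0) stop("scale must be positive in hetero_eval")
  GI <- qgi_mixture(U, h$gi_w, h$gi_lambda, h$gi_lo, h$gi_split, h$gi_hi)
  if (scale != 1) GI <- h$gi_ref * (GI / h$gi_ref)^scale
  cc <- 1 / (1 + GI)
  smult <- clamp((GI / h$gi_ref)^(-h$rho_s), 0.6, 1.5) / h$smult_norm
  sg <- h$sig_s * scale
  ss <- clamp(s_t * h$s_scale * smult * exp(sg * Zs - sg^2 / 2),
              1.08 * delta, 6 * s_t)
  sf <- h$fix_base_sigma * scale
  ff <- clamp(pmax(h$fix_base_mean * exp(sf * Zf - sf^2 / 2),
                   h$kappa * GI * ss), 2.25 * delta, 4000)
  st <- h$sig_t * scale
  ton <- t_on * exp(st * Zt - st^2 / 2)
  data.frame(scan_fraction = cc, gaze_index = GI, fixation_ms = ff,
             saccade_ms = ss, onscreen_bout_ms = ton)
}

# Expected saccades per minute of screen time given per-participant
# parameters (the generator's cycle accounting in closed form).
expected_saccade_rate <- function(p, delta) {
  chain <- p$fixation_ms * p$scan_fraction / (1 - p$scan_fraction)
  ifelse(chain >= p$saccade_ms,
         60000 * (p$fixation_ms * p$scan_fraction +
                    (1 - p$scan_fraction) * delta) /
           (p$fixation_ms * (p$saccade_ms + delta)),
         60000 * p$scan_fraction / p$saccade_ms)
}

# Fixed-point calibration of one behavioral profile against cohort-level
# targets. All internal Monte Carlo uses a fixed local seed, so the result
# is deterministic. See the methods vignette for the model.
calibrate_profile <- function(label, f_t, f_sem, s_t, s_sem, rate_t, px_t,
                              gi_t, p_on, n_group, perf_mean, perf_sd,
                              geometry, rate_hz = 30, off_ms = 5000,
                              on_cv = 0.25, gi_lo = 0.1, gi_hi = 8,
                              kappa = 1.05, rho_s = 0.6,
                              sh_f = 4, sh_s = 3, n_mc = 40000) {
  delta <- 1000 / rate_hz
  f_sd <- f_sem * sqrt(n_group)
  s_sd <- s_sem * sqrt(n_group)
  dr <- with_seed(20210624, list(U = stats::runif(n_mc),
                                 Zf = stats::rnorm(n_mc),
                                 Zs = stats::rnorm(n_mc),
                                 Zt = stats::rnorm(n_mc)))
  h <- list(gi_w = 0.5, gi_lambda = 0.2, gi_lo = gi_lo, gi_split = 3,
            gi_hi = gi_hi, gi_ref = gi_t, rho_s = rho_s, smult_norm = 1,
            sig_s = 0, s_scale = 1, fix_base_mean = f_t, fix_base_sigma = 0,
            kappa = kappa, sig_t = lognormal_sigma(on_cv))
  rate_adj <- rate_t
  for (it in 1:5) {
    Ec <- ((rate_adj * (s_t + delta) / 60000) - delta / f_t) /
      (1 - delta / f_t)
    if (Ec <= 0 || Ec >= 1) {
      stop("infeasible saccade-rate target for this profile", call. = FALSE)
    }
    # Gaze Index distribution: scanner/starer mixture whose weight and
    # scanner exponent are solved so the cohort mean GI and the mean scan
    # fraction E[1/(1+GI)] required by the saccade-rate target are both met.
    gsol <- stats::optim(c(stats::qlogis(h$gi_w), h$gi_lambda), function(p) {
      GI <- qgi_mixture(dr$U, stats::plogis(p[1]), p[2], gi_lo, h$gi_split,
                        gi_hi)
      (mean(GI) / gi_t - 1)^2 + (mean(1 / (1 + GI)) / Ec - 1)^2
    }, method = "Nelder-Mead", control = list(maxit = 500, reltol = 1e-12))
    h$gi_w <- stats::plogis(gsol$par[1])
    h$gi_lambda <- gsol$par[2]
    GI <- qgi_mixture(dr$U, h$gi_w, h$gi_lambda, gi_lo, h$gi_split, gi_hi)
    # saccade-duration coupling: starers get shorter saccades; normalize the
    # multiplier to mean one, then add residual lognormal spread up to the
    # target SD
    smult_raw <- clamp((GI / gi_t)^(-rho_s), 0.6, 1.5)
    h$smult_norm <- mean(smult_raw)
    smult <- smult_raw / h$smult_norm
    var_struct <- stats::var(s_t * smult)
    h$sig_s <- if (var_struct < s_sd^2) {
      lognormal_sigma(sqrt(s_sd^2 - var_struct) / s_t)
    } else 0
    ss0 <- clamp(s_t * smult * exp(h$sig_s * dr$Zs - h$sig_s^2 / 2),
                 1.08 * delta, 6 * s_t)
    h$s_scale <- s_t / mean(ss0)
    # fixation-duration base: lognormal under the structural floor
    # kappa * GI * s (event alternation forces starers into long fixations),
    # solved so the cohort mean and SD match the targets
    floor_vec <- kappa * GI * clamp(ss0 * h$s_scale, 1.08 * delta, 6 * s_t)
    fsol <- stats::optim(
      c(log(f_t), log(max(lognormal_sigma(f_sd / f_t), 1e-3))),
      function(p) {
        ff <- pmax(exp(p[1]) * exp(exp(p[2]) * dr$Zf - exp(2 * p[2]) / 2),
                   floor_vec)
        (mean(ff) / f_t - 1)^2 + (stats::sd(ff) / f_sd - 1)^2
      }, method = "Nelder-Mead",
      control = list(maxit = 600, reltol = 1e-12))
    h$fix_base_mean <- exp(fsol$par[1])
    h$fix_base_sigma <- exp(fsol$par[2])
    p <- hetero_eval(h, s_t, delta, 1, dr$U, dr$Zf, dr$Zs, dr$Zt)
    r <- expected_saccade_rate(p, delta)
    rate_adj <- rate_adj * rate_t / mean(r)
  }
  v_px_ms <- px_t / mean(r * p$saccade_ms)
  speed_deg_s <- pixels_to_degrees(v_px_ms * delta, geometry) / (delta / 1000)
  Tm <- exp(h$sig_t * dr$Zt - h$sig_t^2 / 2)
  t_on <- stats::uniroot(function(T0) {
    mean(T0 * Tm / (T0 * Tm + off_ms)) - p_on
  }, c(50, 500000))$root

  behavior_profile(label = label,
                   fixation_ms_mean = f_t,
                   fixation_ms_shape = sh_f,
                   fixation_ms_sd = f_sd,
                   saccade_ms_mean = s_t,
                   saccade_ms_shape = sh_s,
                   saccade_ms_sd = s_sd,
                   saccade_rate_per_min = rate_t,
                   microfix_ms_mean = delta,
                   saccade_speed_deg_s = speed_deg_s,
                   scan_bout_fraction = Ec,
                   onscreen_fraction = p_on,
                   offscreen_bout_ms_mean = off_ms,
                   onscreen_bout_ms_mean = t_on,
                   onscreen_bout_cv = on_cv,
                   gi_mean = gi_t,
                   heterogeneity = h,
                   saccade_px_per_min = px_t,
                   performance_mean = perf_mean,
                   performance_sd = perf_sd,
                   nominal_rate_hz = rate_hz)
}

profile_cache <- new.env(parent = emptyenv())

#' Default female and male behavioral profiles
#'
#' Returns the two phenotypes the generator is calibrated to, solved so that
#' the cohort expectations of the classified metric suite match the study
#' group means: mean fixation duration 197.6 / 226 ms, 347 / 288 saccades
#' per screen-minute, saccade duration 63.1 / 56.4 ms, saccade distance
#' 35026 / 33542 px per screen-minute, on-screen fraction 0.447 / 0.551 and
#' Gaze Index 2.4 / 3.4 (female / male). Group dispersions are calibrated
#' from the printed standard errors of those means (46 and 47 participants).
#'
#' The scan-fraction heterogeneity is solved in closed form: with
#' per-participant scan fraction `c ~ Beta(alpha, beta)`, the cohort mean
#' saccade rate fixes `E[c]` and the cohort mean Gaze Index fixes
#' `E[1/c] = GI + 1`, which together determine `alpha` and `beta`. A
#' deterministic fixed-point refinement absorbs the clamping and
#' jitter-interaction corrections.
#'
#' Results are cached per geometry/rate combination.
#'
#' @param geometry A [screen_geometry()] (the pixel targets are realized
#'   through this geometry).
#' @param nominal_rate_hz Sampling rate the calibration assumes (default 30).
#' @return List with elements `female` and `male`, each a
#'   [behavior_profile()].
#' @export
default_profiles <- function(geometry = screen_geometry(),
                             nominal_rate_hz = 30) {
  key <- paste(geometry$width_px, geometry$width_cm,
               geometry$viewing_distance_cm, nominal_rate_hz, sep = "_")
  if (!is.null(profile_cache[[key]])) return(profile_cache[[key]])
  female <- calibrate_profile("female",
                              f_t = 197.6, f_sem = 7.2,
                              s_t = 63.1, s_sem = 2.4,
                              rate_t = 347, px_t = 35026,
                              gi_t = 2.4, p_on = 0.447, n_group = 46,
                              perf_mean = 39.9, perf_sd = 16,
                              geometry = geometry, rate_hz = nominal_rate_hz)
  male <- calibrate_profile("male",
                            f_t = 226, f_sem = 6.6,
                            s_t = 56.4, s_sem = 1.8,
                            rate_t = 288, px_t = 33542,
                            gi_t = 3.4, p_on = 0.551, n_group = 47,
                            perf_mean = 38.6, perf_sd = 19,
                            geometry = geometry, rate_hz = nominal_rate_hz)
  out <- list(female = female, male = male)
  profile_cache[[key]] <- out
  out
}

# Draw per-participant generator parameters from a profile's heterogeneity
# model. dispersion_scale scales every between-participant spread (1 =
# calibrated, 0 = homogeneous cohort).
draw_participants <- function(profile, n, dispersion_scale = 1) {
  delta <- 1000 / profile$nominal_rate_hz
  if (is.null(profile$heterogeneity) || dispersion_scale == 0) {
    return(data.frame(scan_fraction = rep(profile$scan_bout_fraction, n),
                      gaze_index = rep((1 - profile$scan_bout_fraction) /
                                         profile$scan_bout_fraction, n),
                      fixation_ms = rep(profile$fixation_ms_mean, n),
                      saccade_ms = rep(profile$saccade_ms_mean, n),
                      onscreen_bout_ms = rep(profile$onscreen_bout_ms_mean, n)))
  }
  hetero_eval(profile$heterogeneity, profile$saccade_ms_mean, delta,
              profile$onscreen_bout_ms_mean,
              U = stats::runif(n), Zf = stats::rnorm(n),
              Zs = stats::rnorm(n), Zt = stats::rnorm(n),
              scale = dispersion_scale)
}

#' Analytic cohort expectations of a calibrated profile
#'
#' Evaluates the generator model's cohort-level expectations (deterministic
#' internal Monte Carlo over the heterogeneity model, fixed internal seed):
#' the metric means that an infinitely long recording of an infinitely large
#' cohort would produce.
#'
#' @param profile A [behavior_profile()].
#' @param geometry A [screen_geometry()].
#' @param n_mc Monte Carlo size.
#' @return Named list of expectations.
#' @export
profile_expectations <- function(profile, geometry = screen_geometry(),
                                 n_mc = 40000) {
  delta <- 1000 / profile$nominal_rate_hz
  p <- with_seed(915001, draw_participants(profile, n_mc))
  r <- expected_saccade_rate(p, delta)
  step_px <- degrees_to_pixels(profile$saccade_speed_deg_s * delta / 1000,
                               geometry)
  list(mean_fixation_ms = mean(p$fixation_ms),
       mean_saccade_ms = mean(p$saccade_ms),
       saccades_per_min = mean(r),
       saccade_px_per_min = mean(r * p$saccade_ms) * step_px / delta,
       gaze_index = mean(p$gaze_index),
       scan_fraction = mean(p$scan_fraction),
       screen_time_fraction = mean(p$onscreen_bout_ms /
                                     (p$onscreen_bout_ms +
                                        profile$offscreen_bout_ms_mean)),
       fixations_per_min = mean(60000 * (1 - p$scan_fraction) /
                                  p$fixation_ms))
}

# --- stream emission --------------------------------------------------------

# Emit one synthetic gaze stream from fixed per-participant parameters.
# Alternating-renewal structure: on-screen episodes of (fixation, scan
# chain) cycles and off-screen gap episodes. All durations live on the
# sample grid, so classification recovers the planned events exactly.
gen_stream_core <- function(participant_id, scan_fraction, fixation_ms,
                            saccade_ms, onscreen_bout_ms, profile, geometry,
                            nominal_rate_hz, task_duration_ms, seed) {
  delta <- 1000 / nominal_rate_hz
  if (delta >= 60) {
    stop("sampling rate too low: one interval must be under 60 ms",
         call. = FALSE)
  }
  m0f <- floor(60 / delta) + 1L              # min fixation intervals (> 60 ms)
  N <- as.integer(floor(task_duration_ms / delta + 1e-9))
  step <- degrees_to_pixels(profile$saccade_speed_deg_s * delta / 1000,
                            geometry)
  W <- geometry$width_px
  H <- geometry$height_px
  margin <- 8

  mu_f <- solve_disc_mu(fixation_ms, profile$fixation_ms_shape, delta, m0f)
  mu_s <- solve_disc_mu(saccade_ms, profile$saccade_ms_shape, delta, 1L)
  chain_ms <- fixation_ms * scan_fraction / (1 - scan_fraction)
  kbar <- (chain_ms + delta) / (saccade_ms + delta)
  q_chain <- if (kbar < 1) chain_ms / saccade_ms else NA_real_
  mbar <- onscreen_bout_ms / (fixation_ms / (1 - scan_fraction))
  m_off <- max(1.5, profile$offscreen_bout_ms_mean / delta - 1)

  cap <- N + 400L
  x <- numeric(cap)
  y <- numeric(cap)
  val <- logical(cap)
  k <- 0L
  cur_x <- 0
  cur_y <- 0

  sh_f <- profile$fixation_ms_shape
  sh_s <- profile$saccade_ms_shape
  rate_f <- sh_f / mu_f
  rate_s <- if (is.na(mu_s)) NA_real_ else sh_s / mu_s
  with_seed(seed, {
    # stationary jitter: bounded so its velocity can never cross the
    # saccade threshold (max displacement ~6 px versus a >40 px threshold
    # step at typical geometry)
    jit <- function(n) stats::runif(n, -2.2, 2.2)
    put_low <- function(n) {
      fresh <- k == 0L || !val[k]
      n2 <- if (fresh) n + 1L else n
      if (fresh) {
        cur_x <<- stats::runif(1, margin, W - margin)
        cur_y <<- stats::runif(1, margin, H - margin)
      }
      idx <- (k + 1L):(k + n2)
      x[idx] <<- cur_x + jit(n2)
      y[idx] <<- cur_y + jit(n2)
      val[idx] <<- TRUE
      k <<- k + n2
      cur_x <<- x[k]
      cur_y <<- y[k]
    }
    put_sacc <- function(ns) {
      th <- stats::runif(1, 0, 2 * pi)
      dx <- step * cos(th)
      dy <- step * sin(th)
      for (i in seq_len(ns)) {
        px <- cur_x + dx
        if (px < margin || px > W - margin) {
          dx <- -dx
          px <- cur_x + dx
        }
        py <- cur_y + dy
        if (py < margin || py > H - margin) {
          dy <- -dy
          py <- cur_y + dy
        }
        k <<- k + 1L
        x[k] <<- px
        y[k] <<- py
        val[k] <<- TRUE
        cur_x <<- px
        cur_y <<- py
      }
    }
    put_off <- function(m) {
      idx <- (k + 1L):(k + m)
      x[idx] <<- NA_real_
      y[idx] <<- NA_real_
      val[idx] <<- FALSE
      k <<- k + m
    }
    draw_nf <- function() {
      max(m0f, as.integer(round(stats::rgamma(1, sh_f, rate_f) / delta)))
    }
    draw_ns <- function() {
      if (is.na(rate_s)) return(1L)
      min(8L, max(1L, as.integer(round(stats::rgamma(1, sh_s, rate_s) / delta))))
    }

    while (k <= N) {
      M <- 1L + stats::rpois(1, max(0, mbar - 1))
      for (j in seq_len(M)) {
        put_low(draw_nf())
        if (k > N) break
        K <- if (kbar >= 1) {
          1L + stats::rpois(1, kbar - 1)
        } else {
          stats::rbinom(1, 1, q_chain)
        }
        if (K > 0) {
          for (kk in seq_len(K)) {
            put_sacc(draw_ns())
            if (kk < K) put_low(1L)
            if (k > N) break
          }
        }
        if (k > N) break
      }
      if (k > N) break
      put_off(1L + stats::rgeom(1, 1 / m_off))
    }
  })

  n_keep <- N + 1L
  samples <- data.frame(t_ms = round((0:N) * delta, 6),
                        x_px = clamp(x[seq_len(n_keep)], 0, W - 1e-9),
                        y_px = clamp(y[seq_len(n_keep)], 0, H - 1e-9),
                        valid = val[seq_len(n_keep)])
  samples$x_px[!samples$valid] <- NA_real_
  samples$y_px[!samples$valid] <- NA_real_
  gaze_stream(participant_id, samples, geometry, nominal_rate_hz,
              task_duration_ms)
}

#' Generate a synthetic gaze stream from a behavioral profile
#'
#' Simulates one participant's recording as an alternating-renewal process:
#' stare bouts (a stationary point with sub-threshold jitter for a
#' gamma-distributed duration), reading-like scan bouts
#' (saccade-microfixation chains, with saccades travelling at the profile's
#' angular speed and reflecting at the screen edges), and off-screen
#' episodes of invalid samples. The sample clock ticks at the nominal rate;
#' identical seeds produce identical streams.
#'
#' @param profile A [behavior_profile()]. The profile means are used as-is
#'   (no between-participant jitter); cohort heterogeneity is applied by
#'   [generate_cohort()].
#' @param geometry A [screen_geometry()].
#' @param nominal_rate_hz Sampling rate (default 30).
#' @param task_duration_ms Task window (default 600000, the 10-minute task).
#' @param seed Integer seed.
#' @param participant_id Label for the stream.
#' @return A [gaze_stream()].
#' @export
generate_stream <- function(profile, geometry = screen_geometry(),
                            nominal_rate_hz = profile$nominal_rate_hz,
                            task_duration_ms = 600000, seed = 1,
                            participant_id = profile$label) {
  stopifnot(inherits(profile, "behavior_profile"))
  gen_stream_core(participant_id,
                  scan_fraction = profile$scan_bout_fraction,
                  fixation_ms = profile$fixation_ms_mean,
                  saccade_ms = profile$saccade_ms_mean,
                  onscreen_bout_ms = profile$onscreen_bout_ms_mean,
                  profile = profile, geometry = geometry,
                  nominal_rate_hz = nominal_rate_hz,
                  task_duration_ms = task_duration_ms, seed = seed)
}

#' Specification of a synthetic cohort
#'
#' @param n_female,n_male Group sizes (defaults 46 and 47).
#' @param profiles List with `female` and `male` [behavior_profile()]s;
#'   `NULL` uses [default_profiles()].
#' @param between_participant_cv Overall dispersion scale applied to the
#'   profiles' calibrated between-participant spreads: `NA` (default) keeps
#'   the calibrated heterogeneity, `0` makes every same-sex participant
#'   identical in expectation.
#' @param task_duration_ms Task window per participant.
#' @param seed Master seed; per-participant substream seeds are derived
#'   deterministically, so regeneration is reproducible regardless of order.
#' @param geometry A [screen_geometry()].
#' @param nominal_rate_hz Sampling rate.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_female = 46, n_male = 47, profiles = NULL,
                        between_participant_cv = NA_real_,
                        task_duration_ms = 600000, seed = 1,
                        geometry = screen_geometry(), nominal_rate_hz = 30) {
  stopifnot(n_female > 0, n_male > 0, task_duration_ms > 0)
  if (!is.na(between_participant_cv) && between_participant_cv < 0) {
    stop("between_participant_cv must be nonnegative", call. = FALSE)
  }
  structure(list(n_female = n_female, n_male = n_male, profiles = profiles,
                 between_participant_cv = between_participant_cv,
                 task_duration_ms = task_duration_ms, seed = seed,
                 geometry = geometry, nominal_rate_hz = nominal_rate_hz),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of gaze streams
#'
#' Draws per-participant generator parameters from each profile's
#' heterogeneity model, then simulates one stream per participant. The
#' task-performance covariate is drawn around the profile's performance
#' distribution for covariate plumbing.
#'
#' @param spec A [cohort_spec()].
#' @return List with `streams` (list of [gaze_stream()]), `cohort`
#'   ([cohort_records()]) and `participants` (the drawn per-participant
#'   generator parameters, useful for calibration checks).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  profiles <- spec$profiles
  if (is.null(profiles)) {
    profiles <- default_profiles(spec$geometry, spec$nominal_rate_hz)
  }
  lam <- if (is.na(spec$between_participant_cv)) 1 else
    spec$between_participant_cv
  nf <- spec$n_female
  nm <- spec$n_male
  ids <- c(sprintf("F%03d", seq_len(nf)), sprintf("M%03d", seq_len(nm)))
  sexes <- c(rep("female", nf), rep("male", nm))
  drawn <- with_seed(spec$seed, {
    pf <- draw_participants(profiles$female, nf, lam)
    pm <- draw_participants(profiles$male, nm, lam)
    perf <- c(clamp(stats::rnorm(nf, profiles$female$performance_mean,
                                 profiles$female$performance_sd), 0, 100),
              clamp(stats::rnorm(nm, profiles$male$performance_mean,
                                 profiles$male$performance_sd), 0, 100))
    list(params = rbind(pf, pm), perf = perf)
  })
  params <- drawn$params
  params$participant_id <- ids
  params$sex_label <- sexes
  streams <- vector("list", nf + nm)
  for (i in seq_len(nf + nm)) {
    prof <- if (i <= nf) profiles$female else profiles$male
    streams[[i]] <- gen_stream_core(
      ids[i],
      scan_fraction = params$scan_fraction[i],
      fixation_ms = params$fixation_ms[i],
      saccade_ms = params$saccade_ms[i],
      onscreen_bout_ms = params$onscreen_bout_ms[i],
      profile = prof, geometry = spec$geometry,
      nominal_rate_hz = spec$nominal_rate_hz,
      task_duration_ms = spec$task_duration_ms,
      seed = derive_seed(spec$seed, i))
  }
  names(streams) <- ids
  cohort <- cohort_records(ids, sexes,
                           performance_pct = if (all(is.na(drawn$perf))) {
                             NA_real_
                           } else drawn$perf)
  list(streams = streams, cohort = cohort, participants = params)
}
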