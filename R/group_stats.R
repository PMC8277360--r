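#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test with the U statistic reported under the min convention,
#' `U = min(U_x, U_y)`, and midrank tie handling. The p-value is exact (by
#' the null permutation distribution) for small tie-free samples
#' (`n_x + n_y <= 16` under `method = "auto"`), and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @param method `"auto"` (default), `"exact"` or `"approx"`. Exact is only
#'   available without ties.
#' @return List with `u_statistic`, `p_value` and `method` used.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(c(x, y)) > 0
  if (method == "exact" && ties) {
    stop("exact p-value unavailable with ties", call. = FALSE)
  }
  use_exact <- switch(method,
                      exact = TRUE,
                      approx = FALSE,
                      auto = !ties && (n1 + n2) <= 16)
  if (use_exact) {
    p <- min(1, 2 * stats::pwilcox(u, n1, n2))
    meth <- "exact"
  } else {
    nn <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    mu <- n1 * n2 / 2
    if (sigma2 <= 0 || u == mu) {
      p <- 1
    } else {
      z <- (u - mu + 0.5) / sqrt(sigma2)   # u <= mu; continuity toward 0
      p <- min(1, 2 * stats::pnorm(z))
    }
    meth <- "approx"
  }
  list(u_statistic = u, p_value = p, method = meth)
}

# Lilliefors-type KS distance of x against a normal with moment-estimated
# parameters.
ks_normal_d <- function(x) {
  n <- length(x)
  u <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - u, u - (i - 1) / n)
}

#' Kolmogorov-Smirnov normality check with Monte Carlo p-value
#'
#' Computes the KS distance of the sample against a normal distribution
#' with moment-estimated mean and standard deviation. Because the parameters
#' are estimated from the data, the classical KS null distribution does not
#' apply; the p-value is obtained by seeded Monte Carlo resampling from the
#' fitted null (the Lilliefors construction).
#'
#' @param x Numeric sample, `length(x) >= 4`, non-constant.
#' @param nsim Number of Monte Carlo replicates (default 10000).
#' @param seed Optional integer seed for the replicates; the global RNG
#'   state is left untouched when given.
#' @return List with `d_statistic`, `p_value` and `nsim`.
#' @export
ks_normality <- function(x, nsim = 10000, seed = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("ks_normality requires n >= 4", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample: normality check undefined",
                              call. = FALSE)
  d <- ks_normal_d(x)
  sim <- function() {
    dsim <- numeric(nsim)
    for (b in seq_len(nsim)) dsim[b] <- ks_normal_d(stats::rnorm(n))
    dsim
  }
  dsim <- if (is.null(seed)) sim() else with_seed(seed, sim())
  list(d_statistic = d,
       p_value = (1 + sum(dsim >= d)) / (nsim + 1),
       nsim = nsim)
}

#' Fourfold (2x2) contingency table
#'
#' Cell layout: `a`, `b` are the outcome-positive and outcome-negative
#' counts in the exposed group; `c`, `d` the same in the unexposed group.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return An object of class `fourfold_table`.
#' @export
fourfold_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("table must have a positive total", call. = FALSE)
  structure(as.list(cells), class = "fourfold_table")
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a d) / (b c)`. When any cell is zero the Haldane-Anscombe
#' correction (add 0.5 to every cell) is applied before the ratio and the
#' interval. The 95% CI is the Woolf log-normal interval.
#'
#' @param t A [fourfold_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
odds_ratio <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "fourfold_table"))
  cells <- c(t$a, t$b, t$c, t$d)
  if ((t$a + t$b) == 0 || (t$c + t$d) == 0 ||
      (t$a + t$c) == 0 || (t$b + t$d) == 0) {
    stop("odds ratio undefined: a table margin is zero", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or),
       ci_low = unname(or * exp(-z * se)),
       ci_high = unname(or * exp(z * se)),
       corrected = corrected)
}

comparison_metrics <- c("screen_time_fraction", "fixations_per_min",
                        "mean_fixation_ms", "mean_interfixation_px",
                        "saccade_px_per_min", "saccades_per_min",
                        "mean_saccade_ms", "gaze_index")

#' Cohort-level sex comparison of the gaze metric suite
#'
#' For each metric, compares the per-participant values between the female
#' and male groups with the two-sided Mann-Whitney U test and reports group
#' means with their standard errors. The task-performance covariate is
#' included when present in the cohort records. Also tabulates the Gaze
#' Index extremes against sex and reports odds ratios: the male odds of
#' being a superstarer (GI above 5) and the female odds of being a
#' superscanner (GI below 1).
#'
#' No multiple-testing adjustment is applied by default; set
#' `p_adjust = "holm"` to emit a Holm-adjusted column alongside.
#'
#' @param metrics Data frame of per-participant rows from
#'   [compute_metrics()].
#' @param cohort A [cohort_records()] data frame; participant ids must match
#'   the metric rows one-to-one.
#' @param metric_names Metrics to compare (default: the full suite).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return List of class `cohort_comparison` with elements `comparisons`
#'   (one row per metric) and `odds_ratios` (one row per GI extreme).
#' @export
compare_cohort <- function(metrics, cohort,
                           metric_names = comparison_metrics,
                           p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (!setequal(metrics$participant_id, cohort$participant_id) ||
      anyDuplicated(metrics$participant_id) ||
      anyDuplicated(cohort$participant_id)) {
    stop("metrics and cohort participant ids must match one-to-one",
         call. = FALSE)
  }
  m <- merge(metrics, cohort, by = "participant_id")
  if ("performance_pct" %in% names(m) && any(!is.na(m$performance_pct)) &&
      !"performance_pct" %in% metric_names) {
    metric_names <- c(metric_names, "performance_pct")
  }
  f <- m[m$sex_label == "female", , drop = FALSE]
  g <- m[m$sex_label == "male", , drop = FALSE]
  if (nrow(f) == 0 || nrow(g) == 0) {
    stop("both sex groups must be nonempty", call. = FALSE)
  }
  rows <- lapply(metric_names, function(nm) {
    xf <- f[[nm]][!is.na(f[[nm]])]
    xm <- g[[nm]][!is.na(g[[nm]])]
    mw <- mann_whitney_u(xf, xm)
    data.frame(metric = nm,
               n_female = length(xf), n_male = length(xm),
               mean_female = mean(xf), sem_female = stats::sd(xf) / sqrt(length(xf)),
               mean_male = mean(xm), sem_male = stats::sd(xm) / sqrt(length(xm)),
               u_statistic = mw$u_statistic, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, rows)
  if (p_adjust == "holm") {
    comparisons$p_holm <- stats::p.adjust(comparisons$p_value, "holm")
  }

  gi <- m$gaze_index
  sex <- m$sex_label
  or_row <- function(contrast, expo, outcome) {
    tab <- fourfold_table(sum(expo & outcome, na.rm = TRUE),
                          sum(expo & !outcome, na.rm = TRUE),
                          sum(!expo & outcome, na.rm = TRUE),
                          sum(!expo & !outcome, na.rm = TRUE))
    o <- tryCatch(odds_ratio(tab), error = function(e) {
      list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    })
    data.frame(contrast = contrast, a = tab$a, b = tab$b, c = tab$c,
               d = tab$d, or = o$or, ci_low = o$ci_low, ci_high = o$ci_high,
               stringsAsFactors = FALSE)
  }
  odds <- rbind(
    or_row("male_gi_gt5", sex == "male", !is.na(gi) & gi > 5),
    or_row("female_gi_lt1", sex == "female", !is.na(gi) & gi < 1)
  )
  structure(list(comparisons = comparisons, odds_ratios = odds),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison>\n")
  print(x$comparisons, digits = 4)
  cat("\nGaze Index extremes:\n")
  print(x$odds_ratios, digits = 3)
  invisible(x)
}
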