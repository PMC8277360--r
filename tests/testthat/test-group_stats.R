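test_that("Mann-Whitney U: worked examples", {
  # complete tie between singletons
  r <- mann_whitney_u(5, 5)
  expect_equal(r$u_statistic, 0.5)
  expect_equal(r$p_value, 1)
  # fully separated 2 vs 2: U = 0, exact p = 2/6
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "exact")
  # interleaved 3 vs 3 matches the permutation oracle
  x <- c(1, 3, 5); y <- c(2, 4, 6)
  r <- mann_whitney_u(x, y)
  o <- mw_enumerate(x, y)
  expect_equal(r$u_statistic, o$u)
  expect_equal(r$p_value, o$p)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("U is symmetric in the two groups (min convention)", {
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1))
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$u_statistic, b$u_statistic)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("exact and approximate p agree closely for 8 vs 8 tie-free data", {
  set.seed(99)
  for (i in 1:25) {
    x <- rnorm(8); y <- rnorm(8, sample(c(0, 1), 1))
    pe <- mann_whitney_u(x, y, method = "exact")$p_value
    pa <- mann_whitney_u(x, y, method = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(mann_whitney_u(c(1, 1), c(1, 2), method = "exact"), "ties")
})

test_that("KS normality check: distance and Monte Carlo p behave correctly", {
  set.seed(7)
  x <- rnorm(200, 5, 2)
  r <- ks_normality(x, nsim = 500, seed = 1)
  # same statistic as the standard KS against the fitted normal
  expect_equal(r$d_statistic,
               unname(stats::ks.test(x, "pnorm", mean(x), sd(x))$statistic))
  # distance invariant under affine maps
  r2 <- ks_normality(3 * x - 10, nsim = 10, seed = 1)
  expect_equal(r2$d_statistic, r$d_statistic)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "n >= 4")
})

test_that("KS p-values separate normal from exponential samples", {
  set.seed(123)
  p_norm <- replicate(20, ks_normality(rnorm(500), nsim = 400)$p_value)
  expect_gte(mean(p_norm > 0.05), 0.95)
  p_exp <- replicate(20, ks_normality(rexp(100), nsim = 400)$p_value)
  expect_gte(mean(p_exp < 0.05), 0.95)
})

test_that("odds ratios with Haldane correction and Woolf interval", {
  expect_equal(odds_ratio(fourfold_table(3, 1, 1, 3))$or, 9)
  expect_equal(odds_ratio(fourfold_table(5, 5, 5, 5))$or, 1)
  r <- odds_ratio(fourfold_table(0, 5, 5, 5))
  expect_true(r$corrected)
  expect_equal(r$or, (0.5 * 5.5) / (5.5 * 5.5))
  expect_lt(r$ci_low, r$or); expect_gt(r$ci_high, r$or)
  # reciprocal identity for nonzero cells
  o1 <- odds_ratio(fourfold_table(4, 7, 2, 9))$or
  o2 <- odds_ratio(fourfold_table(7, 4, 9, 2))$or
  expect_equal(o1 * o2, 1)
  expect_error(odds_ratio(fourfold_table(0, 0, 3, 3)), "margin")
  expect_error(fourfold_table(1.5, 1, 1, 1), "integer")
})

test_that("cohort comparison: identical groups give p = 1 and OR = 1", {
  m <- compute_metrics(classify_events(make_jump_stream()), NULL)
  mets <- do.call(rbind, lapply(1:6, function(i) {
    mi <- m; mi$participant_id <- paste0("p", i); mi
  }))
  coh <- cohort_records(mets$participant_id,
                        rep(c("female", "male"), each = 3))
  cmp <- compare_cohort(mets, coh)
  expect_true(all(cmp$comparisons$p_value == 1))
  # no participant at either GI extreme: OR rows present but undefined
  expect_equal(nrow(cmp$odds_ratios), 2)
})

test_that("cohort comparison matches hand enumeration on a toy cohort", {
  m <- compute_metrics(classify_events(make_jump_stream()), NULL)
  vals <- c(100, 120, 200, 240)
  mets <- do.call(rbind, lapply(1:4, function(i) {
    mi <- m; mi$participant_id <- paste0("p", i)
    mi$mean_fixation_ms <- vals[i]; mi
  }))
  coh <- cohort_records(mets$participant_id,
                        rep(c("female", "male"), each = 2))
  cmp <- compare_cohort(mets, coh, metric_names = "mean_fixation_ms")
  o <- mw_enumerate(vals[1:2], vals[3:4])
  expect_equal(cmp$comparisons$u_statistic, o$u)
  expect_equal(cmp$comparisons$p_value, o$p)
  expect_equal(cmp$comparisons$mean_female, 110)
  expect_equal(cmp$comparisons$sem_male, sd(c(200, 240)) / sqrt(2))
  # id mismatch and empty group errors
  expect_error(compare_cohort(mets, coh[1:3, ]), "one-to-one")
  coh2 <- cohort_records(mets$participant_id, rep("female", 4))
  expect_error(compare_cohort(mets, coh2), "nonempty")
})

test_that("holm-adjusted column is emitted on request", {
  sim <- generate_cohort(small_cohort_spec(seed = 4, n = 4))
  mets <- do.call(rbind, lapply(sim$streams, function(st) {
    compute_metrics(classify_events(st), st)
  }))
  cmp <- compare_cohort(mets, sim$cohort, p_adjust = "holm")
  expect_true("p_holm" %in% names(cmp$comparisons))
  expect_true(all(cmp$comparisons$p_holm >= cmp$comparisons$p_value))
})
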