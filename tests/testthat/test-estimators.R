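test_that("product-limit worked examples are exact", {
  s <- ltrc_sample(c(0, 1, 0), c(2, 3, 4), c(1, 1, 0))
  f0 <- ltrc_cdf(s, correct = FALSE)
  expect_equal(cdf_eval(f0, c(2, 3)), c(1 / 3, 2 / 3))
  expect_equal(f0$total_mass, 2 / 3)
  f1 <- ltrc_cdf(s, correct = TRUE)
  expect_equal(cdf_eval(f1, c(2, 3)), c(1 / 4, 1 / 2))

  # untruncated, uncensored: plain empirical CDF
  e <- ltrc_sample(rep(0, 3), c(1, 2, 3), rep(1, 3))
  fe <- ltrc_cdf(e, correct = FALSE)
  expect_equal(fe$atoms, c(1, 2, 3))
  expect_equal(fe$mass, rep(1 / 3, 3))
})

test_that("estimator equals Kaplan-Meier when truncation is disabled", {
  set.seed(101)
  for (i in 1:15) {
    s <- untruncated_censored(n = 30 + 5 * i)
    f <- ltrc_cdf(s, correct = FALSE)
    expect_equal(cdf_eval(f, f$atoms), km_oracle(s, f$atoms), tolerance = 1e-12)
  }
})

test_that("estimator equals the brute-force Lynden-Bell product when censoring is disabled", {
  set.seed(102)
  for (i in 1:15) {
    s <- truncated_uncensored(n = 30)
    f <- ltrc_cdf(s, correct = FALSE)
    expect_equal(cdf_eval(f, f$atoms), lynden_bell_oracle(s, f$atoms),
                 tolerance = 1e-12)
  }
})

test_that("the risk-set correction shrinks the estimate pointwise and keeps survival positive", {
  set.seed(103)
  for (i in 1:20) {
    s <- random_ltrc(25)
    grid <- sort(unique(s$time))
    f0 <- ltrc_cdf(s, correct = FALSE)
    f1 <- ltrc_cdf(s, correct = TRUE)
    expect_true(all(cdf_eval(f1, grid) <= cdf_eval(f0, grid) + 1e-12))
    expect_true(all(surv_eval(f1, grid) > 0))
    expect_lte(f1$total_mass, 1)
    expect_true(all(diff(cdf_eval(f1, grid)) >= 0))
  }
})

test_that("truncation-distribution estimator reproduces the hand-computed examples", {
  # flat survival at both entries: empirical CDF of the entry times
  s <- ltrc_sample(c(0, 0.5), c(1, 2), c(1, 1))
  g <- truncation_cdf(s, target = ltrc_cdf(s, correct = FALSE))
  expect_equal(g$atoms, c(0, 0.5))
  expect_equal(cdf_eval(g, c(0, 0.5)), c(0.5, 1))

  # an entry time beyond the first event halves the survival weight
  # (hole-corrected target keeps S(U) positive: S(1) = 1/2, weights (1, 2))
  s2 <- ltrc_sample(c(0, 1.5), c(1, 2), c(1, 1))
  g2 <- truncation_cdf(s2)
  expect_equal(g2$atoms, c(0, 1.5))
  expect_equal(cdf_eval(g2, c(0, 1.5)), c(1 / 3, 1))
  expect_equal(g2$total_mass, 1)

  # all entries below the first event: empirical CDF of entries
  s3 <- ltrc_sample(c(-3, -2, -1), c(1, 2, 3), c(1, 1, 1))
  g3 <- truncation_cdf(s3)
  expect_equal(g3$mass, rep(1 / 3, 3))
})

test_that("a hole at or before an entry time raises a named error", {
  s <- ltrc_sample(c(0, 1.5), c(1, 2), c(1, 1))
  f_uncorrected <- ltrc_cdf(s, correct = FALSE)  # S(1) = 0
  expect_error(truncation_cdf(s, target = f_uncorrected),
               class = "ltrcks_hole_error")
  expect_error(nontruncation(s, target = f_uncorrected),
               class = "ltrcks_hole_error")
})

test_that("residual-censoring estimator follows the reversed-indicator Kaplan-Meier", {
  # both records censored: both residuals are D-events, plain ECDF
  q1 <- residual_cdf(ltrc_sample(c(0, 0), c(2, 5), c(0, 0),
                                 require_event = FALSE))
  expect_equal(q1$atoms, c(2, 5))
  expect_equal(cdf_eval(q1, c(2, 5)), c(0.5, 1))

  # first record D-censored: single atom at 5 with full mass
  q2 <- residual_cdf(ltrc_sample(c(0, 0), c(2, 5), c(1, 0)))
  expect_equal(q2$atoms, 5)
  expect_equal(q2$mass, 1)

  # no censored record at all: mass-placement rule puts everything at the
  # largest residual time
  q3 <- residual_cdf(ltrc_sample(0, 3, 1))
  expect_equal(q3$atoms, 3)
  expect_equal(q3$mass, 1)

  # always proper
  set.seed(104)
  for (i in 1:10) {
    q <- residual_cdf(random_ltrc(30))
    expect_equal(sum(q$mass), 1, tolerance = 1e-12)
  }
})

test_that("nontruncation probability estimates match hand computations and stay in (0, 1]", {
  s <- ltrc_sample(c(-3, -2, -1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(nontruncation(s), 1)
  s2 <- ltrc_sample(c(0, 1.5), c(1, 2), c(1, 1))
  expect_equal(nontruncation(s2), 2 / 3)
  set.seed(105)
  for (i in 1:10) {
    g <- nontruncation(random_ltrc(40))
    expect_gt(g, 0)
    expect_lte(g, 1)
  }
})

test_that("nontruncation estimate tracks the design value on simulated data", {
  set.seed(106)
  sc <- scenario_catalog()[[1]]
  s <- simulate_ltrc_sample(sc$groups[[1]], 500)
  expect_lt(abs(nontruncation(s) - pnorm(1 / sqrt(2))), 0.08)
})
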