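test_that("pooled estimator is the weighted mixture of its components", {
  f <- step_cdf(c(1, 2), c(0.5, 0.5))
  expect_equal(pooled_cdf(list(f, f), c(0.5, 0.5))$mass, f$mass)
  expect_equal(pooled_cdf(list(f, f), c(0.5, 0.5))$atoms, f$atoms)

  g <- step_cdf(c(3, 4), c(0.5, 0.5))
  mix <- pooled_cdf(list(f, g), c(0.5, 0.5))
  expect_equal(mix$atoms, 1:4)
  expect_equal(mix$mass, rep(0.25, 4))

  eps <- 1e-9
  near <- pooled_cdf(list(f, g), c(1 - eps, eps))
  expect_equal(cdf_eval(near, f$atoms), cdf_eval(f, f$atoms),
               tolerance = 1e-6)

  expect_error(pooled_cdf(list(f, g), c(1)), "length mismatch")
  expect_error(pooled_cdf(list(f, g), c(0.7, 0.7)), "sum to one")
})

test_that("evaluation window spans the pooled uncensored times only", {
  a <- ltrc_sample(c(0, 0), c(1, 2), c(1, 1), "a")
  b <- ltrc_sample(c(0, 0), c(3, 4), c(1, 1), "b")
  expect_equal(evaluation_window(list(a, b)), c(1, 4))
  expect_equal(evaluation_window(list(ltrc_sample(0, 5, 1))), c(5, 5))
  # censored times are excluded from the window
  a2 <- ltrc_sample(c(0, 0), c(1, 9), c(1, 0), "a")
  b2 <- ltrc_sample(0, 3, 1, "b")
  expect_equal(evaluation_window(list(a2, b2)), c(1, 3))
})

test_that("omnibus statistics vanish iff the group estimates coincide", {
  set.seed(201)
  s <- random_ltrc(30)
  trio <- list(s, s, s)
  expect_equal(ks_statistic(trio), 0)
  expect_equal(cvm_statistic(trio), 0)
  a <- random_ltrc(30, "a")
  b <- random_ltrc(30, "b")
  expect_gt(ks_statistic(list(a, b)), 0)
  expect_gt(cvm_statistic(list(a, b)), 0)
})

test_that("toy two-sample values match hand computation", {
  a <- ltrc_sample(c(-1, -1), c(1, 2), c(1, 1), "a")
  b <- ltrc_sample(c(-1, -1), c(3, 4), c(1, 1), "b")
  expect_equal(ks_statistic(list(a, b), correct = FALSE), 1)
  expect_equal(cvm_statistic(list(a, b), correct = FALSE), 0.375)
})

test_that("k = 2 statistics equal the two-sample reduction identities", {
  set.seed(202)
  for (i in 1:100) {
    s1 <- random_ltrc(sample(15:40, 1), "a")
    s2 <- random_ltrc(sample(15:40, 1), "b")
    id <- two_sample_identities(s1, s2)
    expect_equal(ks_statistic(list(s1, s2)), id$ks, tolerance = 1e-10)
    expect_equal(cvm_statistic(list(s1, s2)), id$cvm, tolerance = 1e-10)
  }
})

test_that("a dense grid never exceeds the atom-grid maximum", {
  set.seed(203)
  for (i in 1:10) {
    sams <- list(random_ltrc(25, "a"), random_ltrc(25, "b"),
                 random_ltrc(25, "c"))
    cdfs <- lapply(sams, ltrc_cdf)
    sizes <- vapply(sams, `[[`, numeric(1), "n")
    p <- sizes / sum(sizes)
    win <- evaluation_window(sams)
    dense <- seq(win[1], win[2], length.out = 10000)
    fmat <- vapply(cdfs, cdf_eval, numeric(length(dense)), t = dense)
    fn <- as.numeric(fmat %*% p)
    dense_max <- max((fmat - fn)^2 %*% sizes)
    expect_lte(dense_max, ks_statistic(sams) + 1e-12)
  }
})

test_that("statistics are invariant to record order and group relabelling", {
  set.seed(204)
  sams <- list(random_ltrc(30, "a"), random_ltrc(35, "b"), random_ltrc(20, "c"))
  shuffled <- lapply(sams, function(s) {
    idx <- sample(s$n)
    ltrc_sample(s$entry[idx], s$time[idx], s$status[idx], s$label)
  })
  expect_equal(ks_statistic(shuffled), ks_statistic(sams))
  expect_equal(cvm_statistic(shuffled), cvm_statistic(sams))
  # relabelling = permuting the list together with its weight vector
  perm <- c(2, 3, 1)
  sizes <- vapply(sams, `[[`, numeric(1), "n")
  w <- sizes / sum(sizes)
  expect_equal(ks_statistic(sams[perm], weights = w[perm]),
               ks_statistic(sams, weights = w))
  expect_equal(cvm_statistic(sams[perm], weights = w[perm]),
               cvm_statistic(sams, weights = w))
})
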