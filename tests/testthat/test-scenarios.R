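test_that("the catalogue holds fifteen three-group scenarios with the stated split", {
  cat15 <- scenario_catalog()
  expect_length(cat15, 15)
  expect_equal(vapply(cat15, `[[`, character(1), "hypothesis"),
               rep(c("H0", "H1"), c(6, 9)))
  expect_true(all(vapply(cat15, function(s) length(s$groups), integer(1)) == 3L))

  s1 <- cat15[[1]]
  for (g in s1$groups) {
    expect_equal(g$x$pars, list(mean = 4, var = 1))
    expect_equal(g$u$pars, list(mean = 3, var = 1))
    expect_equal(g$d$pars, list(rate = 1))
  }
  g15 <- cat15[[15]]$groups[[1]]
  expect_equal(g15$x$family, "exp")
  expect_equal(g15$x$pars$rate, 1 / 10)
  expect_equal(g15$u$pars, list(lo = 0, hi = 10))
  expect_equal(g15$d$pars$rate, 3)
  expect_equal(cat15[[14]]$groups[[1]]$x$pars$kind, "E1")
  expect_equal(cat15[[14]]$groups[[2]]$x$pars$kind, "E2")
  expect_equal(cat15[[15]]$groups[[2]]$x$pars$kind, "L2")

  expect_error(get_scenario(99), "unknown scenario")
})

test_that("simulated samples satisfy the observation scheme", {
  set.seed(601)
  for (id in c(1, 4, 11, 13)) {
    sc <- get_scenario(id)
    s <- simulate_ltrc_sample(sc$groups[[2]], 80)
    expect_equal(s$n, 80)
    expect_true(all(s$entry <= s$time))
    expect_true(all(s$status %in% c(0, 1)))
  }
})

test_that("disabling truncation and censoring yields plain iid draws", {
  set.seed(602)
  spec <- group_spec(dist_norm(4, 1), dist_unif(-1e6, -1e6 + 1),
                     dist_unif(2e6, 2e6 + 1))
  s <- simulate_ltrc_sample(spec, 200)
  expect_true(all(s$status == 1))
  expect_lt(abs(mean(s$time) - 4), 0.3)
  expect_lt(abs(sd(s$time) - 1), 0.2)
})

test_that("incompatible specifications trip the attempt cap", {
  spec <- group_spec(dist_unif(0, 1), dist_unif(10, 11), dist_exp(1))
  expect_error(simulate_ltrc_sample(spec, 10, max_attempts = 1e4),
               class = "ltrcks_acceptance_error")
})

test_that("the unemployment-like fixture has the advertised shape", {
  sams <- fixture_unemployment_like(seed = 7)
  expect_equal(vapply(sams, `[[`, numeric(1), "n"), c(246, 413, 350))
  expect_equal(vapply(sams, function(s) as.character(s$label), character(1)),
               c("none", "one", "two_plus"))
  for (s in sams) {
    expect_true(all(s$entry <= s$time))
    cens <- mean(s$status == 0)
    expect_gt(cens, 0.7)
    expect_lt(cens, 0.9)
  }
  # reproducible given the seed
  expect_identical(fixture_unemployment_like(seed = 7), sams)
})

test_that("the fitted event-time distribution recovers the design truth at large n", {
  set.seed(603)
  sc <- get_scenario(1)
  s <- simulate_ltrc_sample(sc$groups[[1]], 5000)
  f <- ltrc_cdf(s)
  grid <- seq(2.5, 5.5, by = 0.05)
  expect_lt(max(abs(cdf_eval(f, grid) - pnorm(grid, 4, 1))), 0.03)
})
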