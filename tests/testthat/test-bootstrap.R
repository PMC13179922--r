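test_that("obvious-triplet draws respect the truncation filter and censoring algebra", {
  g <- step_cdf(0, 1); f <- step_cdf(1, 1); q <- step_cdf(10, 1)
  expect_equal(unname(draw_obvious_triplet(g, f, q)), c(0, 1, 1))
  # Y = min(X, U + D), censored when the event lies beyond U + D
  q2 <- step_cdf(2, 1); f2 <- step_cdf(5, 1)
  expect_equal(unname(draw_obvious_triplet(g, f2, q2)), c(0, 2, 0))
  # disjoint supports: acceptance impossible
  g5 <- step_cdf(5, 1)
  expect_error(draw_obvious_triplet(g5, f, q, max_attempts = 50),
               class = "ltrcks_acceptance_error")
  # ties U = X are accepted
  expect_equal(unname(draw_obvious_triplet(step_cdf(1, 1), f, q)), c(1, 1, 1))
})

test_that("null resamples keep group sizes, the U <= Y contract and seed determinism", {
  set.seed(401)
  sams <- list(random_ltrc(35, "a"), random_ltrc(45, "b"))
  set.seed(5)
  r1 <- resample_null(sams)
  set.seed(5)
  r2 <- resample_null(sams)
  expect_identical(r1, r2)
  expect_equal(vapply(r1, `[[`, numeric(1), "n"), c(35, 45))
  for (s in r1) expect_true(all(s$entry <= s$time))

  # degenerate point-mass machines reproduce the deterministic triplet
  m <- list(f = step_cdf(1, 1), g = step_cdf(0, 1), q = step_cdf(10, 1),
            gamma = 1, n = 35, label = "a")
  det <- resample_null(sams[1], weights = 1, machines = list(m))
  expect_equal(det[[1]]$entry, rep(0, 35))
  expect_equal(det[[1]]$time, rep(1, 35))
  expect_equal(det[[1]]$status, rep(1, 35))
})

test_that("bootstrap p-values are proportions of exceeding replicates", {
  set.seed(402)
  sams <- list(random_ltrc(30, "a"), random_ltrc(30, "b"))
  kt <- ltrc_ktest(sams, B = 40, seed = 9)
  expect_equal(kt$p_ks, mean(kt$boot_ks >= kt$d_ks))
  expect_equal(kt$p_cvm, mean(kt$boot_cvm >= kt$d_cvm))
  expect_true(all(kt$boot_ks >= 0), all(kt$boot_cvm >= 0))
  expect_true(min(abs(kt$p_ks - (0:40) / 40)) < 1e-12)
  expect_true(min(abs(kt$p_cvm - (0:40) / 40)) < 1e-12)
  # determinism through the seed argument
  kt2 <- ltrc_ktest(sams, B = 40, seed = 9)
  expect_identical(kt[setdiff(names(kt), "seed")],
                   kt2[setdiff(names(kt2), "seed")])
})

test_that("identical groups give zero statistics and p-values of one", {
  set.seed(403)
  s <- random_ltrc(25)
  kt <- ltrc_ktest(list(s, s, s), B = 25, seed = 3)
  expect_equal(kt$d_ks, 0)
  expect_equal(kt$d_cvm, 0)
  expect_equal(kt$p_ks, 1)
  expect_equal(kt$p_cvm, 1)
})

test_that("a large resample from fixed machines recovers the resampling distribution", {
  set.seed(404)
  spec <- group_spec(dist_norm(4, 1), dist_norm(3, 1), dist_exp(1))
  s <- simulate_ltrc_sample(spec, 400)
  f <- ltrc_cdf(s)
  target <- as_proper(f)
  m <- list(f = target, g = truncation_cdf(s, target = f),
            q = residual_cdf(s), gamma = nontruncation(s, target = f),
            n = 20000, label = "big")
  big <- resample_null(list(ltrc_sample(s$entry, s$time, s$status, "big")),
                       weights = 1,
                       machines = list(m))[[1]]
  refit <- as_proper(ltrc_cdf(big))
  grid <- target$atoms
  expect_lt(max(abs(cdf_eval(refit, grid) - cdf_eval(target, grid))), 0.02)
})

test_that("null p-values are close to uniform under the null", {
  set.seed(405)
  spec <- group_spec(dist_norm(4, 1), dist_norm(3, 1), dist_exp(1))
  M <- 400; B <- 99
  p_ks <- numeric(M)
  for (m in 1:M) {
    sams <- lapply(c("a", "b"), function(l) simulate_ltrc_sample(spec, 50, l))
    p_ks[m] <- ltrc_ktest(sams, B = B)$p_ks
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_p <- vapply(grid, function(u) mean(p_ks <= u), numeric(1))
  expect_lt(max(abs(ecdf_p - grid)), 0.08)
})
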