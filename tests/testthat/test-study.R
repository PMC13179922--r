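test_that("warp-speed studies respect their contracts", {
  st <- warp_speed_study(1, sizes = c(40, 40, 40), M = 60,
                         tests = c("KS", "CvM", "LR"), seed = 11)
  expect_s3_class(st, "ltrc_study")
  expect_named(st$rejection, c("KS", "CvM", "LR"))
  expect_true(all(st$rejection >= 0 & st$rejection <= 1))
  expect_equal(st$M, 60L)
  # alpha = 0 rejects nothing
  st0 <- warp_speed_study(1, sizes = c(40, 40, 40), M = 40, alpha = 0,
                          tests = c("KS", "LR"), seed = 12)
  expect_true(all(st0$rejection == 0))
  expect_error(warp_speed_study(1, c(40, 40, 40), M = 10, tests = "XX"),
               "invalid test name")
  expect_error(warp_speed_study(1, c(40, 40, 40), M = 0), "positive")
})

test_that("warp-speed studies are reproducible from the master seed", {
  a <- warp_speed_study(4, sizes = c(30, 30, 30), M = 40,
                        tests = c("KS", "LRM"), seed = 21)
  b <- warp_speed_study(4, sizes = c(30, 30, 30), M = 40,
                        tests = c("KS", "LRM"), seed = 21)
  expect_identical(a$rejection, b$rejection)
  expect_identical(a$pvalues, b$pvalues)
})

test_that("warp-speed p-values are counted with the >= convention over the pooled replicates", {
  st <- warp_speed_study(1, sizes = c(30, 30, 30), M = 50,
                         tests = "KS", seed = 31)
  expect_true(all(st$pvalues >= 1 / 50))  # own replicate always counts
  expect_true(all(st$pvalues <= 1))
})

test_that("warp speed and the full bootstrap agree on a small calibration cell", {
  ws <- warp_speed_study(1, sizes = c(60, 60, 60), M = 300,
                         tests = "KS", seed = 41)
  set.seed(42)
  sc <- get_scenario(1)
  rej <- logical(120)
  for (m in seq_along(rej)) {
    sams <- lapply(1:3, function(j)
      simulate_ltrc_sample(sc$groups[[j]], 60, label = paste0("g", j)))
    rej[m] <- ltrc_ktest(sams, B = 99)$p_ks < 0.05
  }
  expect_lt(abs(ws$rejection[["KS"]] - mean(rej)), 0.07)
})

test_that("study results serialise to the flat table", {
  st <- warp_speed_study(2, sizes = c(25, 30, 35), M = 20,
                         tests = c("KS", "CvM", "LR", "LRE", "LRM", "LRL"),
                         seed = 51)
  df <- as.data.frame(st)
  expect_equal(nrow(df), 6)
  expect_equal(df$scenario, rep(2, 6))
  expect_equal(df$sizes, rep("25,30,35", 6))
  expect_true(all(df$proportion >= 0 & df$proportion <= 1))
  expect_equal(df$seed, rep(51, 6))
})
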