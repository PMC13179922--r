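#' Warp-speed Monte Carlo calibration/power study
#'
#' Runs `M` Monte Carlo trials of a simulation scenario.  In each trial the
#' three group samples are generated, the requested statistics are computed
#' and -- for the omnibus tests -- exactly *one* obvious-bootstrap resample
#' under the null is drawn and its statistics recorded.  After all trials,
#' the p-value of trial `m` is the proportion of the `M` pooled bootstrap
#' statistics at least as large as the trial's observed statistic (the
#' trial's own replicate included), and the rejection proportion is the
#' fraction of trials with p-value below `alpha`.  Pooling one replicate
#' per trial in place of a full `B`-replicate bootstrap is what makes large
#' rejection-proportion studies affordable; it is accurate for large `M`.
#' The weighted rank tests use their asymptotic chi-square p-values within
#' each trial.
#'
#' Each trial runs on its own seed spawned from the master seed, so studies
#' are reproducible and trials are independent.
#'
#' @param scenario an `ltrc_scenario` (see [scenario_catalog()]) or an
#'   integer scenario id.
#' @param sizes integer vector of group sample sizes, one per group.
#' @param M number of Monte Carlo trials.
#' @param alpha significance level.
#' @param tests subset of `c("KS", "CvM", "LR", "LRE", "LRM", "LRL")`.
#' @param weights,correct see [ks_statistic()].
#' @param seed master seed.
#' @return An object of class `ltrc_study`: list with `scenario`,
#'   `hypothesis`, `sizes`, `M`, `alpha`, `seed`, `rejection` (named
#'   proportions) and, for the omnibus tests, `pvalues` (an `M` by tests
#'   matrix of warp-speed p-values).
#' @examples
#' st <- warp_speed_study(1, sizes = c(40, 40, 40), M = 50,
#'                        tests = c("KS", "LR"), seed = 1)
#' st$rejection
#' @export
warp_speed_study <- function(scenario, sizes, M, alpha = 0.05,
                             tests = c("KS", "CvM", "LR", "LRE", "LRM", "LRL"),
                             weights = "proportional", correct = TRUE,
                             seed = NULL) {
  if (is.numeric(scenario)) scenario <- get_scenario(scenario)
  stopifnot(inherits(scenario, "ltrc_scenario"))
  if (M < 1L) stop("M must be a positive integer")
  known <- c("KS", "CvM", "LR", "LRE", "LRM", "LRL")
  bad <- setdiff(tests, known)
  if (length(bad)) stop(sprintf("invalid test name(s): %s",
                                paste(bad, collapse = ", ")))
  omnibus <- intersect(tests, c("KS", "CvM"))
  ranks <- intersect(tests, c("LR", "LRE", "LRM", "LRL"))
  if (!is.null(seed)) set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, M)
  obs_ks <- obs_cvm <- boot_ks <- boot_cvm <- numeric(M)
  rank_p <- matrix(NA_real_, M, length(ranks),
                   dimnames = list(NULL, ranks))
  for (m in seq_len(M)) {
    set.seed(trial_seeds[m])
    samples <- simulate_scenario(scenario, sizes)
    p <- resolve_weights(weights, sizes)
    if (length(omnibus)) {
      st <- omnibus_statistics(samples, p, correct)
      obs_ks[m] <- st$d_ks
      obs_cvm[m] <- st$d_cvm
      res <- resample_null(samples, weights = p, correct = correct)
      stb <- omnibus_statistics(res, p, correct)
      boot_ks[m] <- stb$d_ks
      boot_cvm[m] <- stb$d_cvm
    }
    for (tn in ranks) {
      pq <- rank_test_exponents(tn)
      rank_p[m, tn] <- ltrc_rank_test(samples, pq[1], pq[2],
                                      correct = correct)$p_value
    }
  }
  rejection <- numeric(0)
  pvalues <- NULL
  if (length(omnibus)) {
    pv <- list()
    if ("KS" %in% omnibus) pv$KS <- warp_pvalues(obs_ks, boot_ks)
    if ("CvM" %in% omnibus) pv$CvM <- warp_pvalues(obs_cvm, boot_cvm)
    pvalues <- do.call(cbind, pv)
    rejection <- c(rejection, vapply(pv, function(p) mean(p < alpha),
                                     numeric(1)))
  }
  if (length(ranks)) {
    rejection <- c(rejection,
                   colMeans(rank_p[, ranks, drop = FALSE] < alpha))
  }
  structure(
    list(scenario = scenario$id, hypothesis = scenario$hypothesis,
         sizes = sizes, M = as.integer(M), alpha = alpha, seed = seed,
         rejection = rejection[tests], pvalues = pvalues),
    class = "ltrc_study"
  )
}

# p-value of each trial against the pooled warp-speed null sample
# (>= comparison, own replicate included).
warp_pvalues <- function(obs, boot) {
  m <- length(boot)
  # count of boot >= obs via sorted ranks: O(M log M)
  sb <- sort(boot)
  (m - findInterval(obs, sb, left.open = TRUE)) / m
}

#' @export
print.ltrc_study <- function(x, ...) {
  cat(sprintf(
    "Warp-speed Monte Carlo study: scenario %d (%s), sizes (%s), M = %d, alpha = %g\n",
    x$scenario, x$hypothesis, paste(x$sizes, collapse = ", "), x$M, x$alpha))
  print(round(x$rejection, 4))
  invisible(x)
}

#' @export
as.data.frame.ltrc_study <- function(x, ...) {
  data.frame(
    scenario = x$scenario,
    hypothesis = x$hypothesis,
    sizes = paste(x$sizes, collapse = ","),
    test = names(x$rejection),
    M = x$M,
    alpha = x$alpha,
    proportion = unname(x$rejection),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    row.names = NULL
  )
}
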