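# Small generators used across the suite.  All randomness is consumed from
# the calling test's seed.

# A generic LTRC sample from a normal event time, normal truncation and
# exponential residual censoring with randomised parameters.
random_ltrc <- function(n = 40, label = "g") {
  repeat {
    spec <- group_spec(
      dist_norm(runif(1, 3.5, 4.5), runif(1, 0.5, 2)),
      dist_norm(runif(1, 2.5, 3.5), 1),
      dist_exp(runif(1, 0.5, 2))
    )
    s <- tryCatch(simulate_ltrc_sample(spec, n, label = label),
                  ltrcks_no_event_error = function(e) NULL)
    if (!is.null(s)) return(s)
  }
}

# Right-censored sample with truncation disabled (every entry below the
# smallest observed time), so the LTRC estimator must coincide with
# Kaplan-Meier.
untruncated_censored <- function(n = 40, label = "g", cens_rate = 0.7) {
  x <- rexp(n, 1)
  c0 <- rexp(n, cens_rate)
  time <- pmin(x, c0)
  status <- as.numeric(x <= c0)
  if (!any(status == 1)) status[which.max(time)] <- 1
  ltrc_sample(rep(min(time) - 1, n), time, status, label = label)
}

# Left-truncated sample with censoring disabled (status all one), so the
# LTRC estimator must coincide with the Lynden-Bell estimator.
truncated_uncensored <- function(n = 40, label = "g") {
  # an effectively infinite residual censoring time disables censoring
  spec <- group_spec(dist_norm(4, 1), dist_norm(3, 1), dist_unif(1e5, 2e5))
  simulate_ltrc_sample(spec, n, label = label)
}

# Brute-force Lynden-Bell product over definitionally computed risk sets
# (double loop; independent of the package's vectorised path).
lynden_bell_oracle <- function(sample, t) {
  ev <- sort(unique(sample$time[sample$status == 1]))
  vapply(t, function(tt) {
    s <- 1
    for (x in ev[ev <= tt]) {
      d <- sum(sample$time == x & sample$status == 1)
      r <- sum(sample$entry <= x & x <= sample$time)
      s <- s * (1 - d / r)
    }
    1 - s
  }, numeric(1))
}

# Kaplan-Meier CDF at given times via the survival package (oracle).
km_oracle <- function(sample, t) {
  sf <- survival::survfit(survival::Surv(sample$time, sample$status) ~ 1)
  idx <- findInterval(t, sf$time)
  surv <- c(1, sf$surv)
  1 - surv[idx + 1]
}

# Two-sample reduction identities computed directly from the two fitted
# step estimates (independent of the k-sample code path).
two_sample_identities <- function(s1, s2, correct = TRUE) {
  f1 <- ltrc_cdf(s1, correct = correct)
  f2 <- ltrc_cdf(s2, correct = correct)
  n1 <- s1$n; n2 <- s2$n
  p1 <- n1 / (n1 + n2); p2 <- 1 - p1
  win <- evaluation_window(list(s1, s2))
  grid <- sort(unique(c(f1$atoms, f2$atoms)))
  grid <- grid[grid >= win[1] & grid <= win[2]]
  v1 <- cdf_eval(f1, grid)
  v2 <- cdf_eval(f2, grid)
  fn <- p1 * v1 + p2 * v2
  const <- n1 * p2^2 + n2 * p1^2
  list(
    ks = const * max(abs(v1 - v2))^2,
    cvm = const * sum((v1 - v2)^2 * diff(c(0, fn)))
  )
}
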