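# Obvious-bootstrap machinery: draw (U, X, D) from the estimated truncation,
# event-time and residual-censoring distributions, re-apply the truncation
# filter U <= X, and rebuild the observable triplet
# (U, Y = min(X, U + D), Delta = I[X <= U + D]).
#
# NOTE on the acceptance inequality: the sampling condition of the LTRC
# observation scheme is U <= X, so a draw is *accepted* when U <= X and
# dismissed when X < U.  Published algorithm descriptions sometimes state
# the inequality the other way round; that reading would contradict the
# observation scheme itself and is treated here as a typo.

# Precompute the proper sampling distributions of one group.
resampling_machine <- function(sample, correct = TRUE) {
  f <- ltrc_cdf(sample, correct = correct)
  list(
    f = as_proper(f),
    g = truncation_cdf(sample, target = f),
    q = residual_cdf(sample),
    gamma = nontruncation(sample, target = f),
    n = sample$n,
    label = sample$label
  )
}

#' Draw one observable LTRC triplet from estimated distributions
#'
#' Repeats independent draws `U ~ G`, `X ~ F`, `D ~ Q` until the truncation
#' condition `U <= X` holds (ties accepted), then returns
#' `(U, min(X, U + D), I[X <= U + D])`.
#'
#' @param g,f,q proper [step_cdf()] objects for the truncation, event-time
#'   and residual-censoring distributions (apply [as_proper()] to defective
#'   estimates first).
#' @param max_attempts guard against (near-)disjoint supports of `G` and
#'   `F`.
#' @return Numeric vector `c(entry, time, status)`.
#' @examples
#' g <- step_cdf(0, 1); f <- step_cdf(1, 1); q <- step_cdf(10, 1)
#' draw_obvious_triplet(g, f, q)  # always (0, 1, 1)
#' @export
draw_obvious_triplet <- function(g, f, q, max_attempts = 1e6) {
  for (i in seq_len(max_attempts)) {
    u <- draw_step_cdf(g, 1L)
    x <- draw_step_cdf(f, 1L)
    d <- draw_step_cdf(q, 1L)
    if (u <= x) {
      return(c(entry = u, time = min(x, u + d),
               status = as.numeric(x <= u + d)))
    }
  }
  stop(errorCondition(
    sprintf("no acceptable draw in %g attempts: truncation and event-time supports are (nearly) disjoint", max_attempts),
    class = c("ltrcks_acceptance_error", "ltrcks_error")
  ))
}

#' One obvious-bootstrap resample under the null hypothesis
#'
#' For each group `j` and each of its `n_j` records: draw a group index `j*`
#' with probabilities `p_1, ..., p_k`, then `U` from group `j`'s estimated
#' truncation distribution, `X` from group `j*`'s estimated event-time
#' distribution and `D` from group `j`'s estimated residual-censoring
#' distribution; dismiss the draw unless `U <= X`.  Pooling the event times
#' across groups imposes the null hypothesis while each group keeps its own
#' truncation and censoring mechanisms.
#'
#' Draws are performed in batches; within a batch the order of random draws
#' is group index, `U`, `X` (by ascending source group), `D`, so results are
#' reproducible bit-for-bit given a seed.
#'
#' @param samples list of [ltrc_sample()] objects.
#' @param weights probability vector or `"proportional"`/`"equal"`.
#' @param correct logical; fit the sampling distributions with the risk-set
#'   correction (default).
#' @param machines internal precomputation, see source.
#' @param max_attempts cap on total candidate draws per group.
#' @return A list of [ltrc_sample()] objects with the original group sizes.
#' @export
resample_null <- function(samples, weights = "proportional", correct = TRUE,
                          machines = NULL, max_attempts = 1e7) {
  samples <- as_sample_list(samples)
  sizes <- vapply(samples, `[[`, numeric(1), "n")
  p <- resolve_weights(weights, sizes)
  if (is.null(machines)) {
    machines <- lapply(samples, resampling_machine, correct = correct)
  }
  k <- length(machines)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    m <- machines[[j]]
    # redraw (rare) degenerate resamples with no uncensored event at all,
    # which carry no estimable event distribution
    repeat {
      tri <- draw_null_block(m, machines, p, m$n, max_attempts)
      if (any(tri$status == 1)) break
    }
    out[[j]] <- ltrc_sample(tri$entry, tri$time, tri$status, label = m$label)
  }
  out
}

# Batched rejection sampling of `need` accepted records for one group.
draw_null_block <- function(machine, machines, p, need, max_attempts) {
  k <- length(machines)
  acc_entry <- numeric(0)
  acc_time <- numeric(0)
  acc_status <- numeric(0)
  total <- 0
  rate <- max(machine$gamma, 0.05)
  while (length(acc_entry) < need) {
    m <- max(32L, ceiling(1.3 * (need - length(acc_entry)) / rate))
    total <- total + m
    if (total > max_attempts) {
      stop(errorCondition(
        "bootstrap rejection sampling exceeded the attempt cap",
        class = c("ltrcks_acceptance_error", "ltrcks_error")
      ))
    }
    jstar <- sample.int(k, m, replace = TRUE, prob = p)
    u <- draw_step_cdf(machine$g, m)
    x <- numeric(m)
    for (g in sort(unique(jstar))) {
      idx <- jstar == g
      x[idx] <- draw_step_cdf(machines[[g]]$f, sum(idx))
    }
    d <- draw_step_cdf(machine$q, m)
    ok <- u <= x
    if (any(ok)) {
      acc_entry <- c(acc_entry, u[ok])
      acc_time <- c(acc_time, pmin(x[ok], u[ok] + d[ok]))
      acc_status <- c(acc_status, as.numeric(x[ok] <= u[ok] + d[ok]))
    }
  }
  list(entry = acc_entry[seq_len(need)],
       time = acc_time[seq_len(need)],
       status = acc_status[seq_len(need)])
}
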