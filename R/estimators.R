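#' Product-limit estimator of the event-time distribution under LTRC
#'
#' The distribution function of the event time `X` is estimated by the
#' product-limit (Tsai--Jewell--Wang) estimator
#' `F(t) = 1 - prod_{x_i <= t} (1 - d_i / r_i)`, where the product runs over
#' the distinct uncensored event times, `d_i` counts tied events and `r_i`
#' is the inclusive risk set of [risk_table()].  Without truncation it is the
#' Kaplan--Meier estimator; without censoring it is the Lynden-Bell
#' estimator.
#'
#' A risk set of size one (a *hole*) zeroes the survival estimate from that
#' point on, which is harmful in small truncated samples.  With
#' `correct = TRUE` each risk set is enlarged by one, `d_i / (r_i + 1)`,
#' which keeps the estimated survival strictly positive everywhere at the
#' price of a defective estimate.  The corrected form is the default
#' throughout the package (tests, truncation-distribution weights,
#' bootstrap).
#'
#' @param sample an [ltrc_sample()].
#' @param correct logical; apply the `r + 1` risk-set correction.
#' @return A [step_cdf()] with atoms at the uncensored event times.  The
#'   estimate is defective when the largest observed time is censored or the
#'   correction is on; `support_max` is set to the largest observed time so
#'   [as_proper()] can redistribute the deficit.
#' @examples
#' s <- ltrc_sample(c(0, 1, 0), c(2, 3, 4), c(1, 1, 0))
#' cdf_eval(ltrc_cdf(s, correct = FALSE), c(2, 3))  # 1/3, 2/3
#' cdf_eval(ltrc_cdf(s, correct = TRUE), c(2, 3))   # 1/4, 1/2
#' @export
ltrc_cdf <- function(sample, correct = TRUE) {
  rt <- risk_table(sample)
  denom <- rt$n_risk + if (correct) 1L else 0L
  haz <- rt$n_event / denom
  surv <- cumprod(1 - haz)
  s_prev <- c(1, surv[-length(surv)])
  mass <- s_prev * haz
  keep <- mass > 0  # a hole zeroes every later jump of the uncorrected form
  if (!any(keep)) {
    # single event with unit risk set and no correction: all mass at that time
    keep[1L] <- TRUE
    mass[1L] <- 1
  }
  step_cdf(rt$time[keep], mass[keep], support_max = max(sample$time))
}

#' Estimator of the truncation-time distribution
#'
#' The entry-time distribution `G` is estimated by weighting each observed
#' entry time `U_l` inversely to the estimated survival `S(U_l)` of the
#' event-time distribution, normalised to total mass one.  The target
#' survival is evaluated right-continuously at the entry times, so an entry
#' time tying an event time uses the post-jump value.
#'
#' @param sample an [ltrc_sample()].
#' @param target the fitted event-time [step_cdf()]; defaults to the
#'   hole-corrected [ltrc_cdf()], which guarantees `S(U_l) > 0`.
#' @return A proper [step_cdf()] on the distinct entry times.
#' @examples
#' s <- ltrc_sample(c(0, 1.5), c(1, 2), c(1, 1))
#' truncation_cdf(s)  # jumps 1/3 at 0 and 2/3 at 1.5
#' @export
truncation_cdf <- function(sample, target = ltrc_cdf(sample, correct = TRUE)) {
  stopifnot(is_ltrc_sample(sample), inherits(target, "step_cdf"))
  s_at_entry <- surv_eval(target, sample$entry)
  if (any(s_at_entry <= 1e-12)) {
    stop(errorCondition(
      "estimated survival is zero at an entry time (hole at or before an entry); refit the target with the risk-set correction",
      class = c("ltrcks_hole_error", "ltrcks_error")
    ))
  }
  w <- 1 / s_at_entry
  atoms <- sort(unique(sample$entry))
  mass <- as.numeric(rowsum(w, group = match(sample$entry, atoms)))
  step_cdf(atoms, mass / sum(w), support_max = max(atoms))
}

#' Kaplan--Meier estimator of the residual-censoring distribution
#'
#' Writing the censoring time as `C = U + D`, the residual censoring time
#' `D = C - U` is assumed independent of `(U, X)` on the observable region.
#' Its distribution `Q` is estimated by the ordinary Kaplan--Meier estimator
#' applied to the residual times `V = Y - U` with reversed event indicator
#' `1 - Delta` (a censored event time is an observed value of `D`).  At tied
#' residual times, D-events precede D-censorings (the standard Kaplan--Meier
#' tie rule).  Any remaining mass is placed at the largest residual time, so
#' the returned estimate is always proper and directly samplable.
#'
#' @param sample an [ltrc_sample()].
#' @return A proper [step_cdf()] on residual times.
#' @examples
#' s <- ltrc_sample(c(0, 0), c(2, 5), c(0, 0))
#' residual_cdf(s)  # plain ECDF of {2, 5}
#' @export
residual_cdf <- function(sample) {
  stopifnot(is_ltrc_sample(sample))
  v <- sample$time - sample$entry
  d_event <- 1 - sample$status
  vmax <- max(v)
  ev <- v[d_event == 1]
  if (length(ev) == 0L) {
    return(step_cdf(vmax, 1))
  }
  times <- sort(unique(ev))
  d <- tabulate(match(ev, times), nbins = length(times))
  sv <- sort(v)
  r <- length(v) - findInterval(times, sv, left.open = TRUE)
  haz <- d / r
  surv <- cumprod(1 - haz)
  s_prev <- c(1, surv[-length(surv)])
  mass <- s_prev * haz
  keep <- mass > 0
  cdf <- step_cdf(times[keep], mass[keep], support_max = vmax)
  as_proper(cdf)
}

#' Estimated nontruncation probability
#'
#' The probability `gamma = P(U <= X)` that a population member enters the
#' observed sample, estimated by the harmonic-mean-of-survival form
#' `n / sum_l S(U_l)^{-1}` -- the normalising constant of the
#' truncation-distribution estimator.  Low values mean severe truncation
#' loss.
#'
#' @inheritParams truncation_cdf
#' @return A single probability in `(0, 1]`.
#' @export
nontruncation <- function(sample, target = ltrc_cdf(sample, correct = TRUE)) {
  stopifnot(is_ltrc_sample(sample), inherits(target, "step_cdf"))
  s_at_entry <- surv_eval(target, sample$entry)
  if (any(s_at_entry <= 1e-12)) {
    stop(errorCondition(
      "estimated survival is zero at an entry time; refit the target with the risk-set correction",
      class = c("ltrcks_hole_error", "ltrcks_error")
    ))
  }
  sample$n / sum(1 / s_at_entry)
}
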