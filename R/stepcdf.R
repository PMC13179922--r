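#' Right-continuous step distribution functions
#'
#' A `step_cdf` represents a (possibly defective) discrete distribution
#' function: a finite set of atoms with positive masses whose cumulative sum
#' does not exceed one.  It is the common currency of all estimators in this
#' package: the product-limit estimator of the event-time distribution, the
#' truncation-distribution estimator, the residual-censoring estimator and
#' the pooled null estimator are all `step_cdf` objects.
#'
#' A total mass below one (a *defective* distribution) arises naturally when
#' the largest observed time is censored, or when the risk-set correction of
#' [ltrc_cdf()] is applied.
#'
#' @param atoms strictly increasing numeric vector of jump locations.
#' @param mass positive numeric vector of jump sizes, same length as `atoms`;
#'   `sum(mass)` must not exceed 1 (up to a `1e-10` tolerance).
#' @param support_max optional largest observed time of the sample behind the
#'   estimate; used by [as_proper()] to place any missing mass.
#' @return An object of class `step_cdf` with fields `atoms`, `mass`,
#'   `total_mass` and `support_max`.
#' @seealso [cdf_eval()], [as_proper()], [pooled_cdf()]
#' @examples
#' f <- step_cdf(c(1, 2, 3), c(0.2, 0.3, 0.5))
#' cdf_eval(f, c(0.5, 2, 10))
#' @export
step_cdf <- function(atoms, mass, support_max = NULL) {
  atoms <- as.numeric(atoms)
  mass <- as.numeric(mass)
  if (length(atoms) != length(mass)) {
    stop("'atoms' and 'mass' must have the same length")
  }
  if (length(atoms) == 0L) {
    stop("a step_cdf needs at least one atom")
  }
  if (any(!is.finite(atoms)) || any(!is.finite(mass))) {
    stop("non-finite atom or mass")
  }
  if (is.unsorted(atoms, strictly = TRUE)) {
    stop("'atoms' must be strictly increasing")
  }
  if (any(mass <= 0)) {
    stop("all masses must be positive")
  }
  tm <- sum(mass)
  if (tm > 1 + 1e-10) {
    stop("total mass exceeds one")
  }
  structure(
    list(
      atoms = atoms,
      mass = mass,
      total_mass = min(tm, 1),
      support_max = if (is.null(support_max)) max(atoms) else as.numeric(support_max)
    ),
    class = "step_cdf"
  )
}

#' Evaluate a step distribution function
#'
#' Right-continuous evaluation: `cdf_eval(f, t)` is the sum of the masses at
#' atoms less than or equal to `t`.
#'
#' @param cdf a [step_cdf()] object.
#' @param t numeric vector of evaluation points.
#' @return Numeric vector of the same length as `t`, values in `[0, 1]`.
#' @export
cdf_eval <- function(cdf, t) {
  stopifnot(inherits(cdf, "step_cdf"))
  cum <- cumsum(cdf$mass)
  idx <- findInterval(t, cdf$atoms)
  out <- numeric(length(t))
  pos <- idx > 0L
  out[pos] <- cum[idx[pos]]
  out
}

#' @rdname cdf_eval
#' @export
surv_eval <- function(cdf, t) 1 - cdf_eval(cdf, t)

#' Redistribute missing mass of a defective step CDF
#'
#' A defective estimate cannot be sampled from directly.  Following Efron's
#' convention, the deficit is placed at the largest observation behind the
#' estimate (`support_max`, typically the largest observed time, which may be
#' a censored one), so that the returned distribution is proper.
#'
#' @param cdf a [step_cdf()] object.
#' @param tol deficits at or below this tolerance are absorbed silently.
#' @return A proper `step_cdf` (total mass one).
#' @export
as_proper <- function(cdf, tol = 1e-10) {
  stopifnot(inherits(cdf, "step_cdf"))
  deficit <- 1 - sum(cdf$mass)
  if (deficit <= tol) {
    cdf$mass <- cdf$mass / sum(cdf$mass)
    cdf$total_mass <- 1
    return(cdf)
  }
  target <- max(cdf$support_max, cdf$atoms[length(cdf$atoms)])
  if (target > cdf$atoms[length(cdf$atoms)]) {
    cdf$atoms <- c(cdf$atoms, target)
    cdf$mass <- c(cdf$mass, deficit)
  } else {
    cdf$mass[length(cdf$mass)] <- cdf$mass[length(cdf$mass)] + deficit
  }
  cdf$total_mass <- 1
  cdf
}

#' Draw from a proper step CDF by inverse transform on its atoms
#'
#' @param cdf a proper [step_cdf()]; apply [as_proper()] first if defective.
#' @param n number of draws.
#' @return Numeric vector of `n` atom values.
#' @export
draw_step_cdf <- function(cdf, n) {
  stopifnot(inherits(cdf, "step_cdf"))
  if (cdf$total_mass < 1 - 1e-8) {
    stop("cannot sample from a defective step_cdf; use as_proper() first")
  }
  if (length(cdf$atoms) == 1L) {
    return(rep(cdf$atoms, n))
  }
  cdf$atoms[sample.int(length(cdf$atoms), n, replace = TRUE, prob = cdf$mass)]
}

#' @export
print.step_cdf <- function(x, ...) {
  cat(sprintf(
    "Step CDF with %d atom%s on [%g, %g], total mass %.6g%s\n",
    length(x$atoms), if (length(x$atoms) == 1L) "" else "s",
    x$atoms[1], x$atoms[length(x$atoms)], x$total_mass,
    if (x$total_mass < 1 - 1e-10) " (defective)" else ""
  ))
  invisible(x)
}

#' @export
quantile.step_cdf <- function(x, probs = seq(0, 1, 0.25), ...) {
  cum <- cumsum(x$mass)
  vapply(probs, function(p) {
    if (p > cum[length(cum)] + 1e-12) return(NA_real_)
    x$atoms[which(cum >= p - 1e-12)[1L]]
  }, numeric(1))
}
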