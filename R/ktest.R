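#' Pooled estimator of the common distribution under the null
#'
#' Convex combination `F_n(t) = sum_j p_j F_j(t)` of the per-group step
#' estimates.  Merging the raw samples and re-estimating is *not* a valid
#' alternative under truncation/censoring, because risk sets of one group
#' would be distorted by the other groups; the weighted average of per-group
#' estimates is the pooled estimator used everywhere in this package.
#'
#' @param cdfs list of `k >= 2` [step_cdf()] objects.
#' @param weights probability vector `p_1, ..., p_k` (positive, summing to
#'   one).
#' @return A [step_cdf()] whose atoms are the union of the component atoms.
#' @export
pooled_cdf <- function(cdfs, weights) {
  if (!is.list(cdfs) || length(cdfs) < 2L) {
    stop("need at least two component CDFs")
  }
  if (length(weights) != length(cdfs)) {
    stop("length mismatch between cdfs and weights")
  }
  check_weights(weights)
  atoms <- sort(unique(unlist(lapply(cdfs, `[[`, "atoms"))))
  mass <- numeric(length(atoms))
  for (j in seq_along(cdfs)) {
    idx <- match(cdfs[[j]]$atoms, atoms)
    mass[idx] <- mass[idx] + weights[j] * cdfs[[j]]$mass
  }
  step_cdf(atoms, mass,
           support_max = max(vapply(cdfs, `[[`, numeric(1), "support_max")))
}

check_weights <- function(weights) {
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be strictly positive and sum to one")
  }
  invisible(weights)
}

# Resolve the weight argument ("proportional", "equal" or a numeric vector)
# against the group sizes.
resolve_weights <- function(weights, sizes) {
  if (is.character(weights)) {
    weights <- match.arg(weights, c("proportional", "equal"))
    w <- switch(weights,
                proportional = sizes / sum(sizes),
                equal = rep(1 / length(sizes), length(sizes)))
  } else {
    w <- as.numeric(weights)
    if (length(w) != length(sizes)) {
      stop("length mismatch between weights and samples")
    }
    check_weights(w)
  }
  w
}

#' Identifiable evaluation window of a k-sample comparison
#'
#' The statistics are computed on `[a, b]`, where `a` and `b` are the
#' smallest and largest *uncensored* observed event times pooled over the
#' groups.  Step estimators only change value at uncensored times, so the
#' supremum over the real line is attained inside this window.
#'
#' @param samples list of [ltrc_sample()] objects (or an `ltrcfit`).
#' @return Numeric vector `c(lower, upper)`.
#' @export
evaluation_window <- function(samples) {
  samples <- as_sample_list(samples)
  ev <- unlist(lapply(samples, function(s) s$time[s$status == 1]))
  c(min(ev), max(ev))
}

# Shared computational core of the KS and CvM statistics: evaluates every
# per-group estimate on the pooled uncensored grid restricted to the
# evaluation window and returns both statistics at once (the bootstrap and
# the warp-speed engine need both per resample).
omnibus_statistics <- function(samples, weights = "proportional",
                               correct = TRUE, cdfs = NULL) {
  samples <- as_sample_list(samples)
  k <- length(samples)
  if (k < 2L) stop("need at least two samples")
  sizes <- vapply(samples, `[[`, numeric(1), "n")
  p <- resolve_weights(weights, sizes)
  if (is.null(cdfs)) {
    cdfs <- lapply(samples, ltrc_cdf, correct = correct)
  }
  win <- evaluation_window(samples)
  atoms <- sort(unique(unlist(lapply(cdfs, `[[`, "atoms"))))
  grid <- atoms[atoms >= win[1] & atoms <= win[2]]
  fmat <- vapply(cdfs, cdf_eval, numeric(length(grid)), t = grid)
  if (length(grid) == 1L) fmat <- matrix(fmat, nrow = 1L)
  fn <- as.numeric(fmat %*% p)
  dev2 <- (fmat - fn)^2 %*% sizes  # sum_j n_j (F_j - F_n)^2 on the grid
  d_ks <- max(dev2)
  dfn <- diff(c(0, fn))
  # F_n has an atom exactly where some component jumps; before the window
  # its mass is excluded together with the grid restriction
  d_cvm <- sum(dev2 * dfn)
  list(d_ks = d_ks, d_cvm = d_cvm, weights = p, window = win)
}

#' k-sample Kolmogorov--Smirnov statistic for LTRC data
#'
#' `D_KS = sup_t sum_j n_j (F_j(t) - F_n(t))^2`, with `F_j` the per-group
#' product-limit estimates and `F_n` their pooled convex combination.  The
#' supremum is attained at an uncensored event time inside the window of
#' [evaluation_window()], where it is computed as a maximum.  For `k = 2`
#' the statistic reduces to
#' `(n_1 p_2^2 + n_2 p_1^2) (sup_t |F_1(t) - F_2(t)|)^2`.
#'
#' @param samples list of `k >= 2` [ltrc_sample()] objects (or an `ltrcfit`).
#' @param weights `"proportional"` (`p_j = n_j / n`, the default),
#'   `"equal"`, or a positive probability vector of length `k`.
#' @param correct logical; use the hole-corrected estimator (default).
#' @return The nonnegative statistic value; zero iff all group estimates
#'   coincide on the evaluation grid.
#' @examples
#' a <- ltrc_sample(c(-1, -1), c(1, 2), c(1, 1), "a")
#' b <- ltrc_sample(c(-1, -1), c(3, 4), c(1, 1), "b")
#' ks_statistic(list(a, b), correct = FALSE)  # 1
#' @export
ks_statistic <- function(samples, weights = "proportional", correct = TRUE) {
  omnibus_statistics(samples, weights, correct)$d_ks
}

#' k-sample Cramer--von Mises statistic for LTRC data
#'
#' `D_CvM = sum_j n_j int (F_j(t) - F_n(t))^2 dF_n(t)`, a finite sum over
#' the atoms of the pooled estimate inside the evaluation window.  For
#' `k = 2` it reduces to
#' `(n_1 p_2^2 + n_2 p_1^2) int (F_1 - F_2)^2 dF_n`.
#'
#' @inheritParams ks_statistic
#' @return The nonnegative statistic value.
#' @examples
#' a <- ltrc_sample(c(-1, -1), c(1, 2), c(1, 1), "a")
#' b <- ltrc_sample(c(-1, -1), c(3, 4), c(1, 1), "b")
#' cvm_statistic(list(a, b), correct = FALSE)  # 0.375
#' @export
cvm_statistic <- function(samples, weights = "proportional", correct = TRUE) {
  omnibus_statistics(samples, weights, correct)$d_cvm
}

#' Omnibus k-sample test for LTRC data with bootstrap p-values
#'
#' Computes the Kolmogorov--Smirnov and Cramer--von Mises statistics on the
#' observed samples and approximates their null distributions by the obvious
#' bootstrap under the null: event times are resampled from the pooled
#' estimate (via a freshly drawn group index with probabilities `p_j`),
#' while each group keeps its own estimated truncation and
#' residual-censoring distributions, and the truncation filter `U <= X` is
#' re-applied.  The p-value is the proportion of the `B` replicate
#' statistics at least as large as the observed one.
#'
#' @param samples list of `k >= 2` [ltrc_sample()] objects, or an
#'   [ltrcfit()] object.
#' @param B number of bootstrap resamples.
#' @param weights,correct see [ks_statistic()].
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `ltrc_ktest` with fields `d_ks`, `d_cvm`,
#'   `boot_ks`, `boot_cvm`, `p_ks`, `p_cvm`, `B`, `seed`, `weights`,
#'   `sizes`, `window`.
#' @examples
#' set.seed(7)
#' sams <- lapply(c("a", "b"), function(l)
#'   ltrc_sample(rep(0, 40), rexp(40) + 0.1, rbinom(40, 1, 0.8), l))
#' ltrc_ktest(sams, B = 99, seed = 1)
#' @export
ltrc_ktest <- function(samples, B = 500L, weights = "proportional",
                       correct = TRUE, seed = NULL) {
  samples <- as_sample_list(samples)
  if (B < 1L) stop("B must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(samples, `[[`, numeric(1), "n")
  p <- resolve_weights(weights, sizes)
  obs <- omnibus_statistics(samples, p, correct)
  machines <- lapply(samples, resampling_machine, correct = correct)
  boot_ks <- numeric(B)
  boot_cvm <- numeric(B)
  for (b in seq_len(B)) {
    res <- resample_null(samples, weights = p, correct = correct,
                         machines = machines)
    st <- omnibus_statistics(res, p, correct)
    boot_ks[b] <- st$d_ks
    boot_cvm[b] <- st$d_cvm
  }
  structure(
    list(
      d_ks = obs$d_ks, d_cvm = obs$d_cvm,
      boot_ks = boot_ks, boot_cvm = boot_cvm,
      p_ks = mean(boot_ks >= obs$d_ks),
      p_cvm = mean(boot_cvm >= obs$d_cvm),
      B = as.integer(B), seed = seed,
      weights = p, sizes = sizes, window = obs$window,
      labels = vapply(samples, function(s) as.character(s$label), character(1))
    ),
    class = "ltrc_ktest"
  )
}

#' @export
print.ltrc_ktest <- function(x, ...) {
  cat("k-sample omnibus tests for left-truncated right-censored data\n\n")
  cat(sprintf("groups: %s (n = %s), weights = %s\n",
              paste(x$labels, collapse = ", "),
              paste(x$sizes, collapse = ", "),
              paste(signif(x$weights, 4), collapse = ", ")))
  cat(sprintf("evaluation window: [%.4g, %.4g], B = %d bootstrap resamples\n\n",
              x$window[1], x$window[2], x$B))
  cat(sprintf("  Kolmogorov-Smirnov : D = %.6g, p = %.4g\n", x$d_ks, x$p_ks))
  cat(sprintf("  Cramer-von Mises   : D = %.6g, p = %.4g\n", x$d_cvm, x$p_cvm))
  invisible(x)
}
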