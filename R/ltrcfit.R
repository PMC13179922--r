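#' Fit the nonparametric LTRC model to grouped survival data
#'
#' `ltrcfit()` is the estimation entry point of the package.  For each group
#' it fits the product-limit estimate of the event-time distribution
#' ([ltrc_cdf()]), the truncation-distribution estimate
#' ([truncation_cdf()]), the residual-censoring estimate ([residual_cdf()])
#' and the nontruncation probability ([nontruncation()]).  The fitted
#' object is the input of the omnibus tests ([ltrc_ktest()]), the rank
#' tests ([ltrc_rank_test()]) and the obvious-bootstrap simulator
#' ([simulate.ltrcfit()]).
#'
#' The formula interface uses the counting-process form of
#' [survival::Surv()]: `Surv(entry, time, status) ~ group`.
#'
#' @param x a formula (see details), or a list of [ltrc_sample()] objects.
#' @param data data frame in which the formula is evaluated.
#' @param correct logical; use the hole-corrected estimator (default).
#' @param ... further arguments passed between methods.
#' @return An object of class `ltrcfit`: a list with `samples` (validated
#'   [ltrc_sample()]s in sorted label order), `cdf`, `trunc_cdf`,
#'   `resid_cdf` (per-group [step_cdf()]s), `gamma` (named vector of
#'   nontruncation estimates), `sizes`, `labels`, `correct`.
#' @examples
#' df <- data.frame(entry = c(0, 1, 0, 0.5, 0, 2),
#'                  time = c(2, 3, 4, 2.5, 1, 5),
#'                  status = c(1, 1, 0, 1, 1, 1),
#'                  grp = rep(c("a", "b"), each = 3))
#' fit <- ltrcfit(survival::Surv(entry, time, status) ~ grp, data = df)
#' fit
#' @export
ltrcfit <- function(x, ...) UseMethod("ltrcfit")

#' @rdname ltrcfit
#' @export
ltrcfit.formula <- function(x, data = parent.frame(), correct = TRUE, ...) {
  mf <- stats::model.frame(x, data = data)
  resp <- mf[[1L]]
  if (!inherits(resp, "Surv") || ncol(resp) != 3L) {
    stop("the response must be Surv(entry, time, status) in counting-process form")
  }
  if (ncol(mf) < 2L) stop("a grouping variable is required on the right-hand side")
  grp <- interaction(mf[-1L], drop = TRUE)
  ltrcfit.numeric(resp[, 1L], resp[, 2L], resp[, 3L], grp,
                  correct = correct)
}

#' @rdname ltrcfit
#' @param entry,time,status,group vectors as in [ltrc_sample()], for all
#'   groups stacked.
#' @export
ltrcfit.default <- function(x, ...) {
  stop("no ltrcfit method for this input; supply a formula, vectors, or a list of ltrc_sample objects")
}

#' @rdname ltrcfit
#' @export
ltrcfit.numeric <- function(x, time, status, group, correct = TRUE, ...) {
  entry <- x
  labels <- sort(unique(as.character(group)))
  samples <- lapply(labels, function(l) {
    idx <- as.character(group) == l
    ltrc_sample(entry[idx], time[idx], status[idx], label = l)
  })
  ltrcfit.list(samples, correct = correct)
}

#' @rdname ltrcfit
#' @export
ltrcfit.list <- function(x, correct = TRUE, ...) {
  samples <- as_sample_list(x)
  cdfs <- lapply(samples, ltrc_cdf, correct = correct)
  structure(
    list(
      samples = samples,
      cdf = cdfs,
      trunc_cdf = mapply(function(s, f) truncation_cdf(s, target = f),
                         samples, cdfs, SIMPLIFY = FALSE),
      resid_cdf = lapply(samples, residual_cdf),
      gamma = mapply(function(s, f) nontruncation(s, target = f),
                     samples, cdfs),
      sizes = vapply(samples, `[[`, numeric(1), "n"),
      labels = vapply(samples, function(s) as.character(s$label), character(1)),
      correct = correct
    ),
    class = "ltrcfit"
  )
}

#' @export
print.ltrcfit <- function(x, ...) {
  cat(sprintf("Nonparametric LTRC fit (%d groups%s)\n",
              length(x$samples),
              if (x$correct) ", hole-corrected" else ""))
  df <- data.frame(
    group = x$labels,
    n = x$sizes,
    events = vapply(x$samples, function(s) sum(s$status), numeric(1)),
    gamma = round(unname(x$gamma), 4)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ltrcfit <- function(object, ...) {
  df <- data.frame(
    group = object$labels,
    n = object$sizes,
    events = vapply(object$samples, function(s) sum(s$status), numeric(1)),
    censored = vapply(object$samples, function(s) sum(1 - s$status), numeric(1)),
    gamma = unname(object$gamma),
    total_mass = vapply(object$cdf, `[[`, numeric(1), "total_mass"),
    median = vapply(object$cdf, function(f) quantile(f, 0.5), numeric(1))
  )
  structure(list(table = df, window = evaluation_window(object$samples),
                 correct = object$correct),
            class = "summary.ltrcfit")
}

#' @export
print.summary.ltrcfit <- function(x, ...) {
  cat(sprintf("Nonparametric LTRC fit%s\n",
              if (x$correct) " (hole-corrected risk sets)" else ""))
  print(x$table, row.names = FALSE)
  cat(sprintf("pooled uncensored window: [%.4g, %.4g]\n",
              x$window[1], x$window[2]))
  invisible(x)
}

#' Evaluate fitted distribution functions
#'
#' @param object an [ltrcfit()].
#' @param times numeric evaluation points.
#' @param type which fitted function to evaluate: the event-time CDF or
#'   survival, the truncation CDF, or the residual-censoring CDF.
#' @param ... unused.
#' @return A matrix, `length(times)` by number of groups.
#' @export
predict.ltrcfit <- function(object, times,
                            type = c("cdf", "survival", "truncation", "residual"),
                            ...) {
  type <- match.arg(type)
  src <- switch(type,
                cdf = , survival = object$cdf,
                truncation = object$trunc_cdf,
                residual = object$resid_cdf)
  out <- vapply(src, cdf_eval, numeric(length(times)), t = times)
  if (length(times) == 1L) out <- matrix(out, nrow = 1L)
  if (type == "survival") out <- 1 - out
  dimnames(out) <- list(NULL, object$labels)
  out
}

#' Plot fitted LTRC distribution estimates
#'
#' Step plot of the per-group estimated event-time distribution (or
#' survival) functions.
#'
#' @param x an [ltrcfit()].
#' @param what `"cdf"` or `"survival"`.
#' @param col line colours, recycled over groups.
#' @param xlab,ylab,main usual graphics labels.
#' @param ... passed to [graphics::lines()].
#' @export
plot.ltrcfit <- function(x, what = c("cdf", "survival"),
                         col = seq_along(x$samples) + 1L,
                         xlab = "time", ylab = NULL, main = NULL, ...) {
  what <- match.arg(what)
  if (is.null(ylab)) ylab <- if (what == "cdf") "F(t)" else "S(t)"
  col <- rep_len(col, length(x$samples))
  rng <- range(unlist(lapply(x$cdf, `[[`, "atoms")))
  graphics::plot(rng, c(0, 1), type = "n", xlab = xlab, ylab = ylab,
                 main = main)
  for (j in seq_along(x$cdf)) {
    f <- x$cdf[[j]]
    yy <- cumsum(f$mass)
    if (what == "survival") yy <- 1 - yy
    graphics::lines(stats::stepfun(f$atoms, c(if (what == "cdf") 0 else 1, yy)),
                    col = col[j], do.points = FALSE, ...)
  }
  graphics::legend(if (what == "cdf") "topleft" else "topright",
                   legend = x$labels, col = col, lty = 1, bty = "n")
  invisible(x)
}

#' Simulate LTRC resamples from a fitted model (obvious bootstrap)
#'
#' With `null = TRUE` (default) resamples are drawn under the null
#' hypothesis: event times come from the pooled estimate via a freshly
#' drawn group index, truncation and residual-censoring times from each
#' group's own estimates (see [resample_null()]).  With `null = FALSE`
#' each group resamples from its own three estimated distributions.
#'
#' @param object an [ltrcfit()].
#' @param nsim number of resampled datasets.
#' @param seed optional integer seed.
#' @param null impose the null hypothesis on the event times?
#' @param weights pooling weights, as in [ks_statistic()].
#' @param ... unused.
#' @return A list of `nsim` datasets, each a list of [ltrc_sample()]s.
#' @export
simulate.ltrcfit <- function(object, nsim = 1, seed = NULL, null = TRUE,
                             weights = "proportional", ...) {
  if (!is.null(seed)) set.seed(seed)
  machines <- mapply(function(s, f, g, q, gam) {
    list(f = as_proper(f), g = g, q = q, gamma = gam, n = s$n,
         label = s$label)
  }, object$samples, object$cdf, object$trunc_cdf, object$resid_cdf,
  object$gamma, SIMPLIFY = FALSE)
  p <- resolve_weights(weights, object$sizes)
  k <- length(machines)
  replicate(nsim, simplify = FALSE, {
    if (null) {
      resample_null(object$samples, weights = p, correct = object$correct,
                    machines = machines)
    } else {
      lapply(machines, function(m) {
        own <- list(m)
        tri <- draw_null_block(m, own, 1, m$n, 1e7)
        while (!any(tri$status == 1)) tri <- draw_null_block(m, own, 1, m$n, 1e7)
        ltrc_sample(tri$entry, tri$time, tri$status, label = m$label)
      })
    }
  })
}
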