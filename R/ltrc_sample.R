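#' Validated container for one group of LTRC observations
#'
#' Left-truncated right-censored (LTRC) data record, for each subject, the
#' entry (truncation) time `U`, the observed time `Y = min(X, C)` and the
#' event indicator `Delta = I[X <= C]`, and a subject is sampled only when
#' `U <= X`.  Because the censoring time is assumed never to precede entry
#' (`P(U <= C) = 1`), every observable record satisfies `U <= Y`.
#'
#' @param entry numeric vector of entry/truncation times `U`.
#' @param time numeric vector of observed times `Y`.
#' @param status 0/1 vector; 1 means the event was observed, 0 censored.
#' @param label group identifier.
#' @param require_event logical; demand at least one uncensored record.  The
#'   event-time distribution is only estimable when `TRUE` (the default);
#'   `FALSE` admits fully censored samples, which still carry information on
#'   the residual-censoring distribution ([residual_cdf()]).
#' @return An object of class `ltrc_sample`: a list with fields `entry`,
#'   `time`, `status`, `label` and `n`.
#' @examples
#' ltrc_sample(c(0, 1, 0), c(2, 3, 4), c(1, 1, 0), "A")
#' @export
ltrc_sample <- function(entry, time, status, label = "group",
                        require_event = TRUE) {
  entry <- as.numeric(entry)
  time <- as.numeric(time)
  status <- as.numeric(status)
  n <- length(entry)
  if (n == 0L || length(time) != n || length(status) != n) {
    stop(errorCondition(
      "entry, time and status must be nonempty vectors of equal length",
      class = c("ltrcks_length_error", "ltrcks_error")
    ))
  }
  if (any(!is.finite(entry)) || any(!is.finite(time)) || any(!is.finite(status))) {
    stop(errorCondition(
      "non-finite value in entry, time or status",
      class = c("ltrcks_nonfinite_error", "ltrcks_error")
    ))
  }
  if (!all(status %in% c(0, 1))) {
    stop(errorCondition(
      "status must contain only 0 (censored) and 1 (event)",
      class = c("ltrcks_status_error", "ltrcks_error")
    ))
  }
  bad <- which(entry > time)
  if (length(bad)) {
    stop(errorCondition(
      sprintf(
        "entry exceeds time at record%s %s: LTRC data require U <= Y",
        if (length(bad) > 1L) "s" else "",
        paste(utils::head(bad, 5L), collapse = ", ")
      ),
      class = c("ltrcks_entry_error", "ltrcks_error")
    ))
  }
  if (require_event && !any(status == 1)) {
    stop(errorCondition(
      "no uncensored events: the event-time distribution is not estimable",
      class = c("ltrcks_no_event_error", "ltrcks_error")
    ))
  }
  structure(
    list(entry = entry, time = time, status = status,
         label = label, n = n),
    class = "ltrc_sample"
  )
}

#' @export
print.ltrc_sample <- function(x, ...) {
  cat(sprintf(
    "LTRC sample '%s': n = %d, events = %d (%.1f%% censored)\n",
    x$label, x$n, sum(x$status), 100 * mean(x$status == 0)
  ))
  invisible(x)
}

is_ltrc_sample <- function(x) inherits(x, "ltrc_sample")

# Coerce a list of samples / an ltrcfit / a data.frame-like input to a list
# of validated ltrc_sample objects.
as_sample_list <- function(x) {
  if (is_ltrc_sample(x)) return(list(x))
  if (inherits(x, "ltrcfit")) return(x$samples)
  if (is.list(x) && all(vapply(x, is_ltrc_sample, logical(1)))) return(x)
  stop("expected an ltrc_sample, a list of ltrc_sample objects, or an ltrcfit")
}

#' Event times, death counts and risk sets of an LTRC sample
#'
#' The risk set at an event time `x` uses the inclusive convention
#' `U <= x <= Y`: a subject whose entry time ties the event time is at risk,
#' and records with `U = Y` are legal.  (This differs from the strict
#' inequalities used by `survival::survfit`, which matters in the presence of
#' ties.)
#'
#' @param sample an [ltrc_sample()].
#' @return An object of class `risk_table`: a list with `time` (distinct
#'   uncensored event times, increasing), `n_event` (tied event counts) and
#'   `n_risk` (risk-set sizes).
#' @examples
#' s <- ltrc_sample(c(0, 1, 0), c(2, 3, 4), c(1, 1, 0))
#' risk_table(s)
#' @export
risk_table <- function(sample) {
  stopifnot(is_ltrc_sample(sample))
  ev <- sample$time[sample$status == 1]
  times <- sort(unique(ev))
  d <- as.integer(tabulate(match(ev, times), nbins = length(times)))
  se <- sort(sample$entry)
  st <- sort(sample$time)
  # r = #{U <= x} - #{Y < x}; valid because U <= Y for every record
  r <- findInterval(times, se) - findInterval(times, st, left.open = TRUE)
  structure(
    list(time = times, n_event = d, n_risk = as.integer(r)),
    class = "risk_table"
  )
}

#' @export
print.risk_table <- function(x, ...) {
  print(data.frame(time = x$time, n_event = x$n_event, n_risk = x$n_risk))
  invisible(x)
}

#' @export
as.data.frame.risk_table <- function(x, ...) {
  data.frame(time = x$time, n_event = x$n_event, n_risk = x$n_risk)
}
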