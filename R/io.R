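#' Column schema for delimited LTRC tables
#'
#' LTRC triplets have no standard bioinformatics file format; the package
#' reads and writes plain delimited text with a header and configurable
#' column names.  Status is coded 1 = event observed, 0 = censored.
#'
#' @param entry,time,status,group column names.
#' @param sep field delimiter.
#' @return An object of class `ltrc_schema`.
#' @export
ltrc_schema <- function(entry = "entry", time = "time", status = "status",
                        group = "group", sep = "\t") {
  cols <- c(entry, time, status, group)
  if (anyDuplicated(cols)) stop("the four column names must be distinct")
  structure(list(entry = entry, time = time, status = status, group = group,
                 sep = sep),
            class = "ltrc_schema")
}

#' Read grouped LTRC data from a delimited text file
#'
#' Parses the file under the schema, validates every group through
#' [ltrc_sample()] and reports offending row numbers on failure.  Groups
#' are returned in sorted label order.
#'
#' @param path file path.
#' @param schema an [ltrc_schema()].
#' @return A list of [ltrc_sample()] objects.
#' @export
read_ltrc_table <- function(path, schema = ltrc_schema()) {
  stopifnot(inherits(schema, "ltrc_schema"))
  df <- utils::read.table(path, header = TRUE, sep = schema$sep,
                          stringsAsFactors = FALSE)
  need <- c(schema$entry, schema$time, schema$status, schema$group)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  status <- df[[schema$status]]
  if (!all(status %in% c(0, 1))) {
    bad <- which(!(status %in% c(0, 1)))
    stop(sprintf("status column does not parse to {0,1} at row(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  entry <- as.numeric(df[[schema$entry]])
  time <- as.numeric(df[[schema$time]])
  bad <- which(entry > time)
  if (length(bad)) {
    stop(sprintf("entry exceeds time at row(s) %s: LTRC data require U <= Y",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  labels <- sort(unique(as.character(df[[schema$group]])))
  lapply(labels, function(l) {
    idx <- as.character(df[[schema$group]]) == l
    ltrc_sample(entry[idx], time[idx], status[idx], label = l)
  })
}

#' Write grouped LTRC data to a delimited text file
#'
#' @param samples list of [ltrc_sample()] objects.
#' @param path output file path.
#' @param schema an [ltrc_schema()].
#' @export
write_ltrc_table <- function(samples, path, schema = ltrc_schema()) {
  samples <- as_sample_list(samples)
  df <- do.call(rbind, lapply(samples, function(s) {
    # %.17g keeps doubles exact through a write/read cycle
    out <- data.frame(sprintf("%.17g", s$entry), sprintf("%.17g", s$time),
                      s$status, as.character(s$label),
                      stringsAsFactors = FALSE)
    names(out) <- c(schema$entry, schema$time, schema$status, schema$group)
    out
  }))
  utils::write.table(df, path, sep = schema$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full k-sample analysis on a data file
#'
#' Reads the table, fits the LTRC model, runs the bootstrap omnibus tests
#' and the four weighted rank tests, and returns (and optionally writes as
#' JSON) a machine-readable report.  This is the engine behind the `test`
#' command of the command-line interface.
#'
#' @param input path of the delimited input table.
#' @param out optional path for the JSON report.
#' @param B bootstrap resamples.
#' @param weights `"proportional"` or `"equal"`.
#' @param alpha significance level recorded in the report.
#' @param seed integer seed.
#' @param correct logical; hole-corrected estimation (default).
#' @param schema an [ltrc_schema()].
#' @return The report, an object of class `ltrc_report` (a named list),
#'   invisibly when `out` is given.
#' @export
run_test_command <- function(input, out = NULL, B = 500L,
                             weights = "proportional", alpha = 0.05,
                             seed = 1L, correct = TRUE,
                             schema = ltrc_schema()) {
  samples <- read_ltrc_table(input, schema)
  if (length(samples) < 2L) stop("need at least two groups in the input table")
  fit <- ltrcfit(samples, correct = correct)
  kt <- ltrc_ktest(samples, B = B, weights = weights, correct = correct,
                   seed = seed)
  ranks <- lapply(c("LR", "LRE", "LRM", "LRL"), function(tn) {
    pq <- rank_test_exponents(tn)
    rt <- ltrc_rank_test(samples, pq[1], pq[2], correct = correct)
    list(chi_square = rt$chi_square, df = rt$df, p_value = rt$p_value)
  })
  names(ranks) <- c("LR", "LRE", "LRM", "LRL")
  report <- structure(list(
    input = input,
    groups = fit$labels,
    sizes = as.integer(fit$sizes),
    gamma = round(unname(fit$gamma), 6),
    window = kt$window,
    d_ks = kt$d_ks, p_ks = kt$p_ks,
    d_cvm = kt$d_cvm, p_cvm = kt$p_cvm,
    rank_tests = ranks,
    B = kt$B, alpha = alpha, seed = seed,
    weights = kt$weights, correction = correct
  ), class = "ltrc_report")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' @export
print.ltrc_report <- function(x, ...) {
  cat(sprintf("LTRC k-sample analysis of %s\n", x$input))
  cat(sprintf("groups: %s; sizes: %s; gamma-hat: %s\n",
              paste(x$groups, collapse = ", "),
              paste(x$sizes, collapse = ", "),
              paste(signif(x$gamma, 4), collapse = ", ")))
  cat(sprintf("KS : D = %.6g, p = %.4g\nCvM: D = %.6g, p = %.4g\n",
              x$d_ks, x$p_ks, x$d_cvm, x$p_cvm))
  for (nm in names(x$rank_tests)) {
    rt <- x$rank_tests[[nm]]
    cat(sprintf("%-4s: chi-square = %.6g on %d df, p = %.4g\n",
                nm, rt$chi_square, rt$df, rt$p_value))
  }
  invisible(x)
}

#' Run a simulation study and write its flat result table
#'
#' Engine behind the `simulate` command of the command-line interface:
#' wraps [warp_speed_study()] and serialises the result as tab-delimited
#' text with one row per test.
#'
#' @param scenario scenario id in 1--15.
#' @param sizes integer vector of three group sizes.
#' @param M Monte Carlo trials.
#' @param alpha significance level.
#' @param seed master seed.
#' @param tests tests to run, see [warp_speed_study()].
#' @param out optional output path for the tab-delimited table.
#' @param verbose print the study summary.
#' @return The study result data frame, invisibly when `out` is given.
#' @export
run_simulate_command <- function(scenario, sizes, M, alpha = 0.05, seed = 1L,
                                 tests = c("KS", "CvM", "LR", "LRE", "LRM", "LRL"),
                                 out = NULL, verbose = FALSE) {
  if (length(sizes) != 3L || any(sizes < 1)) {
    stop("sizes must be three positive integers")
  }
  st <- warp_speed_study(get_scenario(scenario), sizes = sizes, M = M,
                         alpha = alpha, tests = tests, seed = seed)
  if (verbose) print(st)
  df <- as.data.frame(st)
  if (!is.null(out)) {
    utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
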