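# Daily cumulative-incidence monitoring with a binomial likelihood-ratio
# signal rule: the policy cohort is compared each day against the average of
# the historical cohorts; a signal is a run of days with likelihood ratio
# above exp(1.96) ~= 7.1 sustained for at least 30 days.

#' Default signal threshold
#'
#' The likelihood-ratio threshold `exp(1.96)` rounded to one decimal (7.1),
#' an approximate analogue of a two-sided alpha of 0.05.
#'
#' @return A single number.
#' @export
default_signal_threshold <- function() {
  round_half_up(exp(1.96), 1)
}

#' Daily cumulative incidence of an endpoint
#'
#' The percentage of cohort members who experienced the endpoint on or before
#' each follow-up day. The denominator is the fixed cohort size for all 365
#' days (no censoring).
#'
#' @param event_table An `event_time_table` (or a tibble with an `event_day`
#'   column; `NA` means the endpoint did not occur).
#' @param n Cohort size (denominator). Defaults to the event table's cohort
#'   size.
#' @param follow_up_days Length of follow-up (default 365).
#' @return An `incidence_series` tibble with columns `day`, `x` (cumulative
#'   event count) and `ci` (cumulative incidence, percent).
#' @export
cumulative_incidence <- function(event_table, n = NULL,
                                 follow_up_days = 365L) {
  n <- n %||% attr(event_table, "n") %||% nrow(event_table)
  if (is.null(n) || n < 1) {
    stop_ss("cumulative incidence needs a denominator n >= 1",
            "invalid_argument")
  }
  days <- event_table$event_day
  days <- days[!is.na(days)]
  if (any(days < 1 | days > follow_up_days)) {
    stop_ss("event days must lie within follow-up (1..follow_up_days)",
            "invalid_argument")
  }
  x <- cumsum(tabulate(days, nbins = follow_up_days))
  structure(
    tibble::tibble(day = seq_len(follow_up_days), x = x, ci = 100 * x / n),
    n = n, endpoint = attr(event_table, "endpoint"),
    class = c("incidence_series", class(tibble::tibble()))
  )
}

#' Generalized two-sample binomial likelihood ratio
#'
#' Ratio of the binomial likelihood of the observed counts under the
#' unrestricted two-proportion model to the likelihood under a common
#' proportion:
#' `log lr = x1 log(p1/p) + (n1-x1) log((1-p1)/(1-p)) + x0 log(p0/p) +
#' (n0-x0) log((1-p0)/(1-p))` with `p1 = x1/n1`, `p0 = x0/n0`,
#' `p = (x1+x0)/(n1+n0)`; zero-count terms contribute zero. The statistic is
#' two-sided by construction and always at least 1, with equality exactly
#' when the two sample proportions coincide; `2 log lr` equals the G-squared
#' statistic of the corresponding 2x2 contingency table.
#'
#' @param x1,n1 Event count and denominator of the policy cohort.
#' @param x0,n0 Pooled event count and denominator of the historical cohorts.
#' @param log Return the log likelihood ratio instead.
#' @return Vectorized likelihood ratio (>= 1), or its logarithm.
#' @export
likelihood_ratio <- function(x1, n1, x0, n0, log = FALSE) {
  k <- max(length(x1), length(x0), length(n1), length(n0))
  x1 <- rep_len(x1, k); n1 <- rep_len(n1, k)
  x0 <- rep_len(x0, k); n0 <- rep_len(n0, k)
  if (any(n1 < 1 | n0 < 1 | x1 < 0 | x0 < 0 | x1 > n1 | x0 > n0)) {
    stop_ss("counts must satisfy 0 <= x <= n with n >= 1", "invalid_argument")
  }
  p1 <- x1 / n1
  p0 <- x0 / n0
  p <- (x1 + x0) / (n1 + n0)
  term <- function(count, prop_num, prop_den) {
    ifelse(count == 0, 0, count * (base::log(prop_num) - base::log(prop_den)))
  }
  loglr <- term(x1, p1, p) + term(n1 - x1, 1 - p1, 1 - p) +
    term(x0, p0, p) + term(n0 - x0, 1 - p0, 1 - p)
  loglr <- pmax(loglr, 0)  # guard tiny negative rounding; true value is >= 0
  if (log) loglr else exp(loglr)
}

#' Maximal above-threshold runs of a likelihood-ratio series
#'
#' @param lr Daily likelihood ratios (or their logs with
#'   `log_input = TRUE`).
#' @param threshold Signal threshold on the likelihood-ratio scale
#'   (default [default_signal_threshold()]); days count when `lr` is strictly
#'   greater.
#' @param sustain_days Minimum run length for a signal (default 30).
#' @param log_input Interpret `lr` as log likelihood ratios.
#' @return A tibble of maximal runs: `start_day`, `end_day`, `length`,
#'   `classification` (`"sustained-to-end"` for a run reaching the final day,
#'   otherwise `"transient"`), and `signal` (length >= `sustain_days`).
#' @export
signal_intervals <- function(lr, threshold = default_signal_threshold(),
                             sustain_days = 30L, log_input = FALSE) {
  above <- if (log_input) lr > base::log(threshold) else lr > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- tibble::tibble(
    start_day = starts[keep], end_day = ends[keep],
    length = r$lengths[keep]
  )
  out$classification <- ifelse(out$end_day == length(lr),
                               "sustained-to-end", "transient")
  out$signal <- out$length >= sustain_days
  out
}

#' Compare the policy cohort with the historical cohorts for one endpoint
#'
#' The cumulative-incidence difference (`cid`) is the policy cohort's daily
#' cumulative incidence minus the unweighted mean of the historical cohorts'
#' cumulative incidences (percentage points). The likelihood ratio compares
#' the policy counts against the pooled historical counts (a likelihood
#' requires counts; pooling and averaging differ when cohort sizes differ -
#' both quantities are surfaced in the output).
#'
#' @param policy_series An `incidence_series` for the policy cohort.
#' @param historical_series List of `incidence_series` for the historical
#'   cohorts.
#' @param threshold Signal threshold (default [default_signal_threshold()]).
#' @param sustain_days Minimum sustained run length (default 30).
#' @return An `endpoint_comparison` list: `series` (tibble with `day`,
#'   `ci_policy`, `ci_hist_mean`, `cid`, `log_lr`, `lr`, `direction`) and
#'   `report` (endpoint, threshold, sustain days, the interval table of
#'   [signal_intervals()], overall `signal`, `onset_day`, `max_cid`,
#'   `max_cid_day`).
#' @export
compare_cohorts <- function(policy_series, historical_series,
                            threshold = default_signal_threshold(),
                            sustain_days = 30L) {
  if (inherits(historical_series, "incidence_series")) {
    historical_series <- list(historical_series)
  }
  len <- nrow(policy_series)
  if (any(vapply(historical_series, nrow, integer(1)) != len)) {
    stop_ss("policy and historical series must cover the same follow-up",
            "invalid_argument")
  }
  n1 <- attr(policy_series, "n")
  n0 <- sum(vapply(historical_series, attr, numeric(1), "n"))
  x0 <- Reduce(`+`, lapply(historical_series, function(s) s$x))
  ci_hist_mean <- Reduce(`+`, lapply(historical_series, function(s) s$ci)) /
    length(historical_series)
  cid <- policy_series$ci - ci_hist_mean
  log_lr <- likelihood_ratio(policy_series$x, n1, x0, n0, log = TRUE)
  series <- tibble::tibble(
    day = policy_series$day,
    ci_policy = policy_series$ci,
    ci_hist_mean = ci_hist_mean,
    cid = cid,
    log_lr = log_lr,
    lr = exp(log_lr),
    direction = sign(cid)
  )
  intervals <- signal_intervals(log_lr, threshold, sustain_days,
                                log_input = TRUE)
  qualifying <- intervals[intervals$signal, ]
  imax <- which.max(abs(cid))
  report <- list(
    endpoint = attr(policy_series, "endpoint"),
    threshold = threshold,
    sustain_days = as.integer(sustain_days),
    n_policy = n1,
    n_historical_pooled = n0,
    intervals = intervals,
    signal = nrow(qualifying) > 0,
    onset_day = if (nrow(qualifying) > 0) qualifying$start_day[1] else
      NA_integer_,
    classification = if (nrow(qualifying) > 0)
      qualifying$classification[1] else "none",
    max_cid = if (length(imax)) cid[imax] else NA_real_,
    max_cid_day = if (length(imax)) imax else NA_integer_
  )
  structure(list(series = series, report = report),
            class = "endpoint_comparison")
}

#' Monitor every endpoint of a cohort set
#'
#' Ascertains each endpoint in every cohort, computes the daily cumulative
#' incidence, and compares the policy cohort against the historical cohorts.
#'
#' @param bundle A `claims_bundle`.
#' @param cohorts A `cohort_set` from [build_all_cohorts()].
#' @param endpoints Endpoint names (default: the full catalog).
#' @param threshold,sustain_days Signal rule parameters.
#' @return A named list of `endpoint_comparison` objects.
#' @export
monitor_endpoints <- function(bundle, cohorts,
                              endpoints = endpoint_catalog()$name,
                              threshold = default_signal_threshold(),
                              sustain_days = 30L) {
  roles <- vapply(cohorts, `[[`, character(1), "role")
  policy <- cohorts[[which(roles == "policy")]]
  historical <- cohorts[roles == "historical"]
  out <- lapply(endpoints, function(ep) {
    pol <- cumulative_incidence(ascertain_endpoints(bundle, policy, ep)[[1]])
    his <- lapply(historical, function(coh) {
      cumulative_incidence(ascertain_endpoints(bundle, coh, ep)[[1]])
    })
    compare_cohorts(pol, his, threshold = threshold,
                    sustain_days = sustain_days)
  })
  names(out) <- endpoints
  out
}

#' @export
print.endpoint_comparison <- function(x, ...) {
  r <- x$report
  cat(sprintf("<endpoint_comparison: %s>\n", r$endpoint %||% "?"))
  cat(sprintf("  signal: %s%s\n", r$signal,
              if (r$signal) sprintf(" (%s, onset day %d)", r$classification,
                                    r$onset_day) else ""))
  cat(sprintf("  max cumulative-incidence difference: %+.1f pp on day %d\n",
              r$max_cid, r$max_cid_day))
  invisible(x)
}
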