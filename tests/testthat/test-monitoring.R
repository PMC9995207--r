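# independent oracles ---------------------------------------------------------

# likelihood ratio via direct evaluation of the four binomial probability
# masses (independent of the analytic log formula in the package)
loglr_pmf_oracle <- function(x1, n1, x0, n0) {
  p1 <- x1 / n1
  p0 <- x0 / n0
  p <- (x1 + x0) / (n1 + n0)
  dbinom(x1, n1, p1, log = TRUE) + dbinom(x0, n0, p0, log = TRUE) -
    dbinom(x1, n1, p, log = TRUE) - dbinom(x0, n0, p, log = TRUE)
}

# G-squared statistic of the 2x2 table (observed vs expected cell counts)
g2_oracle <- function(x1, n1, x0, n0) {
  obs <- c(x1, n1 - x1, x0, n0 - x0)
  rows <- c(n1, n0)
  cols <- c(x1 + x0, n1 + n0 - x1 - x0)
  expd <- outer(rows, cols) / (n1 + n0)
  expd <- c(expd[1, 1], expd[1, 2], expd[2, 1], expd[2, 2])
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / expd[keep]))
}

# -----------------------------------------------------------------------------

test_that("cumulative incidence counts events on or before each day", {
  et <- fake_events(c(3, 3, 200), 4)
  ci <- cumulative_incidence(et)
  expect_equal(ci$ci[1:2], c(0, 0))
  expect_equal(ci$ci[3:199], rep(50, 197))
  expect_equal(ci$ci[200:365], rep(75, 166))
  expect_true(all(diff(ci$x) >= 0))
  expect_equal(ci$ci[365], 100 * 3 / 4)  # ends at the overall proportion

  expect_equal(cumulative_incidence(fake_events(integer(0), 5))$ci,
               rep(0, 365))
  expect_equal(cumulative_incidence(fake_events(rep(1, 5), 5))$ci,
               rep(100, 365))
  expect_error(cumulative_incidence(fake_events(1, 1), n = 0),
               class = "invalid_argument")
  expect_error(cumulative_incidence(fake_events(400, 2)),
               class = "invalid_argument")
})

test_that("the likelihood ratio is exactly 1 at equal proportions", {
  expect_identical(likelihood_ratio(10, 100, 30, 300), 1)
  expect_identical(likelihood_ratio(0, 100, 0, 300), 1)
  expect_identical(likelihood_ratio(100, 100, 300, 300), 1)
  expect_identical(likelihood_ratio(0, 50, 0, 50), 1)
})

test_that("the likelihood ratio matches the binomial pmf oracle", {
  # spec-anchored case: x1=30/100 vs pooled x0=45/300
  expect_equal(likelihood_ratio(30, 100, 45, 300, log = TRUE),
               loglr_pmf_oracle(30, 100, 45, 300), tolerance = 1e-12)
  expect_equal(likelihood_ratio(30, 100, 45, 300, log = TRUE), 5.13,
               tolerance = 0.01)

  set.seed(401)
  for (i in 1:300) {
    n1 <- sample(2:400, 1)
    n0 <- sample(2:400, 1)
    x1 <- sample(0:n1, 1)
    x0 <- sample(0:n0, 1)
    ll <- likelihood_ratio(x1, n1, x0, n0, log = TRUE)
    expect_gte(ll, 0)  # lr >= 1 always
    expect_equal(ll, max(loglr_pmf_oracle(x1, n1, x0, n0), 0),
                 tolerance = 1e-9)
    expect_equal(2 * ll, max(g2_oracle(x1, n1, x0, n0), 0), tolerance = 1e-9)
  }
  expect_error(likelihood_ratio(5, 4, 1, 10), class = "invalid_argument")
  expect_error(likelihood_ratio(-1, 4, 1, 10), class = "invalid_argument")
  expect_error(likelihood_ratio(1, 0, 1, 10), class = "invalid_argument")
})

test_that("signal runs are maximal, classified, and need 30 days to signal", {
  make_lr <- function(days_above) {
    lr <- rep(1, 365)
    lr[days_above] <- 50
    lr
  }
  # 29 days above threshold: interval recorded, but no signal
  iv <- signal_intervals(make_lr(100:128))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_day, 100)
  expect_equal(iv$end_day, 128)
  expect_false(any(iv$signal))
  # run reaching the last day: sustained to end
  iv <- signal_intervals(make_lr(69:365))
  expect_true(iv$signal)
  expect_equal(iv$classification, "sustained-to-end")
  expect_equal(iv$start_day, 69)
  # interior run: transient
  iv <- signal_intervals(make_lr(125:232))
  expect_true(iv$signal)
  expect_equal(iv$classification, "transient")
  # flat series: no intervals at all
  expect_equal(nrow(signal_intervals(rep(1, 365))), 0)
  # threshold crossing is strict
  expect_equal(nrow(signal_intervals(rep(7.1, 365), threshold = 7.1)), 0)
})

test_that("identical cohorts produce lr = 1 everywhere and no signal", {
  et <- fake_events(c(10, 50, 200), 100)
  pol <- cumulative_incidence(et)
  his <- list(cumulative_incidence(et), cumulative_incidence(et),
              cumulative_incidence(et))
  cmp <- compare_cohorts(pol, his)
  expect_true(all(cmp$series$lr == 1))
  expect_true(all(cmp$series$cid == 0))
  expect_false(cmp$report$signal)
  expect_equal(nrow(cmp$report$intervals), 0)
  expect_equal(cmp$report$classification, "none")
})

test_that("the difference averages cohorts while the lr pools counts", {
  # two historical cohorts of different sizes: day-1 incidences 50% (50/100)
  # and 0% (0/300); unweighted mean 25%, pooled proportion 50/400 = 12.5%
  pol <- cumulative_incidence(fake_events(rep(1, 25), 100))
  h1 <- cumulative_incidence(fake_events(rep(1, 50), 100))
  h2 <- cumulative_incidence(fake_events(integer(0), 300))
  cmp <- compare_cohorts(pol, list(h1, h2))
  expect_equal(cmp$series$ci_hist_mean[1], 25)
  expect_equal(cmp$series$cid[1], 0)  # 25% policy - 25% averaged
  expect_equal(cmp$series$direction[1], 0)
  # but the likelihood compares 25/100 against pooled 50/400
  expect_equal(cmp$series$log_lr[1],
               likelihood_ratio(25, 100, 50, 400, log = TRUE))
  expect_gt(cmp$series$lr[1], 1)
})

test_that("a strong injected difference is a sustained signal with onset", {
  pol <- cumulative_incidence(fake_events(rep(30, 40), 100))
  his <- lapply(1:3, function(i) {
    cumulative_incidence(fake_events(rep(30, 10), 100))
  })
  cmp <- compare_cohorts(pol, his)
  expect_true(cmp$report$signal)
  expect_equal(cmp$report$classification, "sustained-to-end")
  expect_equal(cmp$report$onset_day, 30)
  expect_equal(cmp$report$max_cid, 30)
  expect_equal(cmp$series$direction[365], 1)
})

test_that("mismatched follow-up lengths are rejected", {
  pol <- cumulative_incidence(fake_events(1, 10))
  short <- cumulative_incidence(fake_events(1, 10), follow_up_days = 100L)
  expect_error(compare_cohorts(pol, list(short)),
               class = "invalid_argument")
})

test_that("the default threshold is exp(1.96) to one decimal", {
  expect_equal(default_signal_threshold(), 7.1)
})
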