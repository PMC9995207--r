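cohort_2019 <- function(bundle) build_cohort(bundle, 2019, role = "policy")

test_that("nth infliximab dispensation counts distinct service dates", {
  b <- fixture_bundle()
  coh <- cohort_2019(b)
  get_day <- function(tab, id) tab$event_day[tab$patient_id == id]
  # P01 has follow-up dispensations on days 10, 66, 122 and the escalated
  # dispensation on day 169
  expect_equal(get_day(nth_infliximab_dispensation(b, coh, 1), "P01"), 10L)
  expect_equal(get_day(nth_infliximab_dispensation(b, coh, 3), "P01"), 122L)
  expect_equal(get_day(nth_infliximab_dispensation(b, coh, 4), "P01"), 169L)
  # P07's two same-day records on day 10 collapse to one event
  expect_equal(get_day(nth_infliximab_dispensation(b, coh, 1), "P07"), 10L)
  expect_true(is.na(get_day(nth_infliximab_dispensation(b, coh, 2), "P07")))
})

test_that("event days are monotone in n for every patient", {
  cfg <- scenario_config(seed = 17, cohort_years = 2018:2019,
                         patients_per_year = 300)
  b <- simulate_claims(cfg)
  coh <- build_cohort(b, 2019, role = "policy")
  prev_inflx <- NULL
  prev_vis <- NULL
  for (k in 1:4) {
    cur_inflx <- nth_infliximab_dispensation(b, coh, k)$event_day
    cur_vis <- health_service_events(b, coh, "physician_visit", k)$event_day
    if (k > 1) {
      expect_true(all(cur_inflx >= prev_inflx, na.rm = TRUE))
      expect_true(all(cur_vis >= prev_vis, na.rm = TRUE))
      # an n-th event requires an (n-1)-th
      expect_true(all(!is.na(prev_inflx[!is.na(cur_inflx)])))
    }
    prev_inflx <- cur_inflx
    prev_vis <- cur_vis
  }
})

test_that("dose escalation uses the running mean with an inclusive 1.25 ratio", {
  b <- fixture_bundle()
  coh <- cohort_2019(b)
  esc <- dose_escalation(b, coh)
  # P01: 500 mg after a uniform 400 mg history -> ratio exactly 1.25, day 169
  expect_equal(esc$event_day[esc$patient_id == "P01"], 169L)
  expect_equal(esc$product[esc$patient_id == "P01"], "originator_infliximab")
  # P07 never escalates (same-day split keeps the daily dose at baseline)
  expect_true(is.na(esc$event_day[esc$patient_id == "P07"]))
})

test_that("a ratio just below 1.25 is not an escalation", {
  dp <- tibble::tibble(
    patient_id = "A",
    service_date = as.Date(c("2019-05-01", "2019-06-26", "2019-10-01")),
    drug_class = "originator_infliximab", brand = "Remicade",
    quantity_mg = c(300, 300, 370), days_supply = 56L,
    prescriber_specialty = "gastroenterology", payer_accepted = TRUE
  )
  b <- mini_bundle(dispensations = dp)
  esc <- dose_escalation(b, cohort_2019(b))
  expect_true(is.na(esc$event_day[esc$patient_id == "A"]))
  # raising the final quantity to exactly 1.25x the history triggers it
  dp$quantity_mg[3] <- 375
  b2 <- mini_bundle(dispensations = dp)
  esc2 <- dose_escalation(b2, cohort_2019(b2))
  expect_equal(esc2$event_day[esc2$patient_id == "A"], 27L)
})

test_that("a first-ever dispensation in follow-up can never escalate", {
  dp <- tibble::tibble(
    patient_id = c("A", "A"),
    service_date = as.Date(c("2019-04-15", "2019-10-15")),
    drug_class = "originator_infliximab", brand = "Remicade",
    quantity_mg = c(300, 900), days_supply = 56L,
    prescriber_specialty = "gastroenterology", payer_accepted = TRUE
  )
  # B's only dispensation on record is in follow-up: no earlier average
  dpB <- tibble::tibble(
    patient_id = "B", service_date = as.Date("2019-09-20"),
    drug_class = "originator_infliximab", brand = "Remicade",
    quantity_mg = 900, days_supply = 56L,
    prescriber_specialty = "gastroenterology", payer_accepted = TRUE
  )
  b <- mini_bundle(dispensations = dplyr::bind_rows(dp, dpB))
  coh <- mini_cohort(c("A", "B"))
  esc <- dose_escalation(b, coh)
  expect_equal(esc$event_day[esc$patient_id == "A"], 41L)  # 2019-10-15
  expect_true(is.na(esc$event_day[esc$patient_id == "B"]))
})

test_that("escalation is invariant to splitting a dispensation in two", {
  b <- fixture_bundle()
  coh <- cohort_2019(b)
  base <- dose_escalation(b, coh)
  dp <- b$dispensations
  i <- which(dp$patient_id == "P01" & dp$quantity_mg == 500)
  split <- dp[i, ]
  split$quantity_mg <- 250
  dp$quantity_mg[i] <- 250
  b2 <- claims_bundle(b$enrollment, dplyr::bind_rows(dp, split), b$visits,
                      b$hospital)
  again <- dose_escalation(b2, cohort_2019(b2))
  expect_equal(base$event_day, again$event_day)
})

test_that("ascertainment never reads past the follow-up window", {
  b <- fixture_bundle()
  cs <- build_all_cohorts(b, c(2018, 2019))
  # P01's escalated dispensation (2020-02-20) is beyond the 2018 cohort's
  # 365-day follow-up and must not register there
  esc2018 <- dose_escalation(b, cs[["2018"]])
  expect_true(is.na(esc2018$event_day[esc2018$patient_id == "P01"]))
  n1 <- nth_infliximab_dispensation(b, cs[["2018"]], 1)
  expect_equal(n1$event_day[n1$patient_id == "P01"], 51L)  # 2018-10-25
})

test_that("other-biologic and antibiotic endpoints pick the first event day", {
  b <- fixture_bundle()
  coh <- cohort_2019(b)
  ob <- switch_to_other_biologic(b, coh)
  expect_equal(ob$event_day[ob$patient_id == "P07"], 150L)
  expect_true(is.na(ob$event_day[ob$patient_id == "P01"]))
  ab <- antibiotic_dispensation(b, coh)
  expect_equal(ab$event_day[ab$patient_id == "P07"], 132L)
})

test_that("new prednisone use honours the 183-day corticosteroid washout", {
  b <- fixture_bundle()
  coh <- cohort_2019(b)
  pr <- new_prednisone_use(b, coh)
  # P07: day-50 dispensation qualifies; the day-80 refill is blocked by the
  # first dispensation's supply interval
  expect_equal(pr$event_day[pr$patient_id == "P07"], 50L)

  # an earlier corticosteroid whose supply reaches into the washout window
  # disqualifies the only prednisone dispensation entirely
  dp <- tibble::tibble(
    patient_id = c("A", "A", "A"),
    service_date = as.Date(c("2019-05-01", "2019-07-17", "2019-10-24")),
    drug_class = c("originator_infliximab", "other_systemic_corticosteroid",
                   "prednisone"),
    brand = c("Remicade", "dexamethasone", "prednisone"),
    quantity_mg = c(400, 100, 1200), days_supply = c(56L, 30L, 30L),
    prescriber_specialty = "gastroenterology", payer_accepted = TRUE
  )
  b2 <- mini_bundle(dispensations = dp)
  pr2 <- new_prednisone_use(b2, mini_cohort("A"))
  expect_true(is.na(pr2$event_day[pr2$patient_id == "A"]))
})

test_that("health-service endpoints map visits and stays to the right days", {
  b <- fixture_bundle()
  coh <- cohort_2019(b)
  day_of <- function(tab, id) tab$event_day[tab$patient_id == id]
  expect_equal(day_of(health_service_events(b, coh, "gastroenterologist_visit"),
                      "P07"), 22L)
  expect_equal(day_of(health_service_events(b, coh, "physician_visit", 1),
                      "P07"), 6L)
  expect_equal(day_of(health_service_events(b, coh, "physician_visit", 2),
                      "P07"), 22L)
  expect_equal(day_of(health_service_events(b, coh, "physician_visit", 3),
                      "P07"), 41L)
  expect_true(is.na(day_of(health_service_events(b, coh, "physician_visit", 4),
                           "P07")))
  expect_equal(day_of(health_service_events(b, coh, "ed_visit"), "P07"), 88L)
  # stay admitted pre-index, discharged day 30: discharge counts, admission
  # does not, and an elective stay is no emergency admission
  expect_equal(day_of(health_service_events(b, coh, "hospital_discharge"),
                      "P07"), 30L)
  expect_true(is.na(day_of(health_service_events(b, coh, "emergency_admission"),
                           "P07")))
  expect_error(health_service_events(b, coh, "spa_visit"),
               class = "invalid_argument")
  expect_error(health_service_events(b, coh, "ed_visit", n = 2),
               class = "invalid_argument")
})

test_that("switch curves have fixed denominators and sensible extremes", {
  b <- fixture_bundle()
  coh <- cohort_2019(b)
  sc <- biosimilar_switch_curve(b, coh)
  expect_equal(attr(sc, "uptake_pct"), 0)  # nobody in the cohort switches
  all_curve <- sc[sc$stratum == "all", ]
  expect_true(all(all_curve$pct_switched == 0))

  # everyone switching on day 1 jumps the curve to 100% immediately
  dp <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = 2),
    service_date = as.Date(rep(c("2019-05-01", "2019-09-05"), 2)),
    drug_class = rep(c("originator_infliximab", "biosimilar_infliximab"), 2),
    brand = "x", quantity_mg = 400, days_supply = 56L,
    prescriber_specialty = "gastroenterology", payer_accepted = TRUE
  )
  b2 <- mini_bundle(dispensations = dp)
  sc2 <- biosimilar_switch_curve(b2, mini_cohort(c("A", "B")))
  a2 <- sc2[sc2$stratum == "all", ]
  expect_true(all(a2$pct_switched == 100))
  expect_equal(attr(sc2, "uptake_pct"), 100)
})
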