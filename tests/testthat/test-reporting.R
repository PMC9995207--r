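share_bundle <- function() {
  # May 2019: 10 infliximab dispensations, 4 biosimilar; June empty;
  # July: pediatric-only dispensations, none accepted by the public plan
  dp <- tibble::tibble(
    patient_id = c(rep("A", 10), rep("K", 2)),
    service_date = as.Date(c(rep("2019-05-10", 6), rep("2019-05-20", 4),
                             rep("2019-07-15", 2))),
    drug_class = c(rep("originator_infliximab", 6),
                   rep("biosimilar_infliximab", 4),
                   rep("originator_infliximab", 2)),
    brand = "x", quantity_mg = 400, days_supply = 56L,
    prescriber_specialty = "gastroenterology",
    payer_accepted = c(rep(TRUE, 10), FALSE, FALSE)
  )
  en <- tibble::tibble(
    patient_id = c("A", "K"),
    start_date = as.Date("2015-01-01"), end_date = as.Date("2021-12-31"),
    birth_year = c(1980L, 2010L), sex = c("male", "female")
  )
  claims_bundle(enrollment = en, dispensations = dp)
}

test_that("monthly share divides biosimilar by all infliximab dispensations", {
  ms <- monthly_biosimilar_share(share_bundle())
  adult_may <- ms[ms$age_group == "adult" & ms$coverage == "all" &
                    ms$month == as.Date("2019-05-01"), ]
  expect_equal(adult_may$n_dispensations, 10L)
  expect_equal(adult_may$share, 40)
})

test_that("months without dispensations are flagged missing, not zero", {
  ms <- monthly_biosimilar_share(share_bundle())
  adult_june <- ms[ms$age_group == "adult" & ms$coverage == "all" &
                     ms$month == as.Date("2019-06-01"), ]
  expect_true(adult_june$missing)
  expect_true(is.na(adult_june$share))
  # pediatric July dispensations exist overall but none payer-accepted
  ped_july <- ms[ms$age_group == "pediatric" & ms$month == as.Date("2019-07-01"), ]
  expect_equal(ped_july$share[ped_july$coverage == "all"], 0)
  expect_true(is.na(ped_july$share[ped_july$coverage == "payer_accepted"]))
})

test_that("the patient-flow table prints counts with one-decimal percentages", {
  fake_cohort <- function(year, role, users, ibd, excl) {
    structure(list(definition = cohort_definition(year),
                   members = character(ibd - sum(excl)),
                   flow = patient_flow(users, ibd, excl[1], excl[2], excl[3],
                                       excl[4]),
                   role = role),
              class = "cohort")
  }
  cs <- structure(
    list("2018" = fake_cohort(2018, "historical", 8, 8, c(0, 0, 0, 1)),
         "2019" = fake_cohort(2019, "policy", 8, 6, c(0, 0, 0, 0))),
    class = "cohort_set"
  )
  tab <- patient_flow_table(cs)
  expect_equal(tab[["2018 (historical)"]][tab$row == "excluded_no_pharmacare"],
               "1 (12.5)")
  expect_equal(tab[["2019 (policy)"]][tab$row == "excluded_switchers"],
               "0 (0.0)")
  expect_equal(tab[["2019 (policy)"]][tab$row == "final_cohort"], "6")
})

test_that("characteristics summarise age, sex and utilisation per cohort", {
  en <- tibble::tibble(
    patient_id = c("A", "B"),
    start_date = as.Date("2015-01-01"), end_date = as.Date("2020-12-31"),
    birth_year = c(1979L, 1973L),  # ages 40 and 46 at the 2019 index
    sex = c("male", "female")
  )
  dp <- tibble::tibble(
    patient_id = c("A", "B"),
    service_date = as.Date(c("2019-05-01", "2019-05-02")),
    drug_class = "originator_infliximab", brand = "Remicade",
    quantity_mg = 400, days_supply = 56L,
    prescriber_specialty = "gastroenterology", payer_accepted = TRUE
  )
  b <- claims_bundle(enrollment = en, dispensations = dp)
  cs <- structure(list("2019" = mini_cohort(c("A", "B"))),
                  class = "cohort_set")
  tab <- characteristics_table(cs, b)
  col <- tab[["2019 (policy)"]]
  expect_equal(col[tab$row == "age_mean_sd"], "43.0 (4.2)")  # sd(c(40,46))
  expect_equal(col[tab$row == "male_n_pct"], "1 (50.0)")

  # single-patient cohort: mean equals the age, SD is not defined
  cs1 <- structure(list("2019" = mini_cohort("A")), class = "cohort_set")
  tab1 <- characteristics_table(cs1, b)
  expect_equal(tab1[["2019 (policy)"]][tab1$row == "age_mean_sd"],
               "40.0 (NA)")
})

test_that("table renderers are pure: identical bytes on identical inputs", {
  b <- fixture_bundle()
  cs <- build_all_cohorts(b, c(2018, 2019))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  readr::write_csv(patient_flow_table(cs), file.path(d1, "flow.csv"))
  readr::write_csv(patient_flow_table(cs), file.path(d2, "flow.csv"))
  readr::write_csv(characteristics_table(cs, b), file.path(d1, "chars.csv"))
  readr::write_csv(characteristics_table(cs, b), file.path(d2, "chars.csv"))
  for (f in c("flow.csv", "chars.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("panels are rendered one per endpoint, shaded only when signalling", {
  pol <- cumulative_incidence(fake_events(rep(30, 40), 100))
  his <- list(cumulative_incidence(fake_events(rep(30, 10), 100)))
  signal_cmp <- compare_cohorts(pol, his)
  null_cmp <- compare_cohorts(pol, list(pol))
  dir <- withr::local_tempdir()
  files <- render_panels(
    list(dose_escalation = signal_cmp, ed_visit = null_cmp),
    dir, formats = "png"
  )
  expect_length(files, 2)
  expect_true(all(file.exists(files)))
  expect_equal(nrow(null_cmp$report$intervals), 0)   # nothing to shade
  expect_gt(nrow(signal_cmp$report$intervals), 0)
  expect_error(render_panels(list(), dir), class = "invalid_argument")
})

test_that("rounding is half away from zero at one decimal", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.35, 1), 0.4)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(21.8308, 1), 21.8)
})
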