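# Hand-enumerable claims fixture around the 2019 cohort (identification
# window 2019-03-07..2019-09-04, index 2019-09-05, day 1 = index).
#
# P01  included; member of the 2018 and 2019 cohorts; follow-up infliximab on
#      days 10/66/122 and a dose-escalated dispensation (500 mg vs 400 mg
#      baseline, ratio exactly 1.25) on day 169
# P02  originator user failing all three IBD criteria -> never a candidate
# P03  discontinuer: only in-window dispensation 170 days pre-index
# P04  switcher: biosimilar dispensation 10 days pre-index
# P05  lack of enrollment at index (IBD via two gastroenterology visits)
# P06  no payer-accepted in-window dispensation (IBD via flagged hospital stay)
# P07  included pediatric patient carrying the endpoint micro-cases:
#      same-day split infliximab records (day 10), qualifying prednisone on
#      day 50 with a disqualified chain refill on day 80, antibiotic day 132,
#      other biologic day 150, gastroenterologist visit day 22, physician
#      visits days 6/41, ED visit day 88, hospital stay admitted pre-index
#      and discharged day 30 (elective)

fixture_bundle <- function() {
  enrollment <- tibble::tribble(
    ~patient_id, ~start_date, ~end_date, ~birth_year, ~sex,
    "P01", "2015-01-01", "2020-12-31", 1980L, "male",
    "P02", "2016-01-01", "2020-12-31", 1975L, "female",
    "P03", "2015-06-01", "2020-12-31", 1990L, "male",
    "P04", "2015-06-01", "2020-12-31", 1985L, "female",
    "P05", "2015-01-01", "2019-08-31", 1970L, "male",
    "P06", "2015-01-01", "2020-12-31", 1965L, "female",
    "P07", "2012-01-01", "2021-12-31", 2010L, "female"
  )
  enrollment$start_date <- as.Date(enrollment$start_date)
  enrollment$end_date <- as.Date(enrollment$end_date)

  orig <- function(id, date, qty = 400, spec = "gastroenterology",
                   accepted = TRUE, supply = 56L, brand = "Remicade") {
    tibble::tibble(patient_id = id, service_date = as.Date(date),
                   drug_class = "originator_infliximab", brand = brand,
                   quantity_mg = qty, days_supply = supply,
                   prescriber_specialty = spec, payer_accepted = accepted)
  }
  other <- function(id, date, class, qty, supply, brand) {
    tibble::tibble(patient_id = id, service_date = as.Date(date),
                   drug_class = class, brand = brand, quantity_mg = qty,
                   days_supply = as.integer(supply),
                   prescriber_specialty = "other", payer_accepted = TRUE)
  }

  dispensations <- dplyr::bind_rows(
    # P01: 2018 history + follow-up days 10/66/122 + escalation day 169
    orig("P01", c("2018-03-15", "2018-05-10", "2018-07-05", "2018-08-30",
                  "2018-10-25", "2018-12-20", "2019-02-14", "2019-04-11",
                  "2019-06-06", "2019-08-01",
                  "2019-09-14", "2019-11-09", "2020-01-04")),
    orig("P01", "2020-02-20", qty = 500),
    # P02: in-window but no IBD markers
    orig("P02", c("2019-05-01", "2019-07-20"), spec = "other"),
    # P03: discontinuer
    orig("P03", "2019-03-19"),
    # P04: pre-index switcher (non-ASCII brand checks encoding round trips)
    orig("P04", c("2019-05-15", "2019-07-01")),
    other("P04", "2019-08-26", "biosimilar_infliximab", 400, 56,
          "Biosimèra"),
    # P05: excluded for enrollment
    orig("P05", c("2019-06-10", "2019-08-05"), spec = "other"),
    # P06: nothing payer-accepted in window
    orig("P06", c("2019-04-02", "2019-05-28", "2019-07-23"), spec = "other",
         accepted = FALSE),
    # P07: baseline + same-day split records on day 10 + event dispensations
    orig("P07", c("2019-06-15", "2019-08-10"), qty = 300),
    orig("P07", c("2019-09-14", "2019-09-14"), qty = 150),
    other("P07", "2019-10-24", "prednisone", 1200, 30, "prednisone"),
    other("P07", "2019-11-23", "prednisone", 1200, 30, "prednisone"),
    other("P07", "2020-01-14", "antibiotic_ibd", 7000, 14, "ciprofloxacin"),
    other("P07", "2020-02-01", "other_biologic", 80, 14, "adalimumab")
  )

  visit <- function(id, date, specialty = "other", setting = "outpatient",
                    flag = FALSE, provider = "physician") {
    tibble::tibble(patient_id = id, service_date = as.Date(date),
                   provider_type = provider, specialty = specialty,
                   setting = setting, diagnosis_flag_ibd = flag)
  }
  visits <- dplyr::bind_rows(
    visit("P05", c("2019-01-15", "2019-04-20"),
          specialty = "gastroenterology"),
    visit("P07", "2019-03-01", flag = TRUE),
    visit("P07", "2019-09-10"),
    visit("P07", "2019-09-26", specialty = "gastroenterology"),
    visit("P07", "2019-10-15", provider = "nurse_practitioner"),
    visit("P07", "2019-12-01", setting = "emergency_department")
  )

  hospital <- tibble::tibble(
    patient_id = c("P06", "P07"),
    admission_date = as.Date(c("2019-02-10", "2019-08-20")),
    discharge_date = as.Date(c("2019-02-14", "2019-10-04")),
    admission_category = c("emergency", "elective"),
    diagnosis_flag_ibd = c(TRUE, FALSE)
  )

  switchsignal::claims_bundle(enrollment, dispensations, visits, hospital)
}

# minimal single-table bundle helpers used by endpoint micro-tests
mini_cohort <- function(ids, year = 2019, role = "policy") {
  structure(
    list(definition = switchsignal::cohort_definition(year),
         members = ids,
         flow = switchsignal::patient_flow(length(ids), length(ids),
                                           0L, 0L, 0L, 0L),
         role = role),
    class = "cohort"
  )
}

mini_bundle <- function(dispensations = NULL, visits = NULL, hospital = NULL,
                        ids = NULL) {
  ids <- ids %||% unique(c(dispensations$patient_id, visits$patient_id,
                           hospital$patient_id))
  enrollment <- tibble::tibble(
    patient_id = ids, start_date = as.Date("2015-01-01"),
    end_date = as.Date("2021-12-31"), birth_year = 1980L, sex = "male"
  )
  switchsignal::claims_bundle(enrollment, dispensations, visits, hospital)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fabricate an event-time table directly (for monitoring-layer tests)
fake_events <- function(days, n, endpoint = "test") {
  structure(
    tibble::tibble(
      patient_id = sprintf("X%03d", seq_len(n)),
      event_day = as.integer(c(days, rep(NA_integer_, n - length(days))))
    ),
    endpoint = endpoint, n = n,
    class = c("event_time_table", class(tibble::tibble()))
  )
}
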