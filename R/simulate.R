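# Seeded synthetic-claims generator. Emulates the structure the monitoring
# analysis assumes: yearly waves of originator-infliximab users on a roughly
# 8-weekly dispensation cadence, an attrition ladder (discontinuation,
# pre-index switching, enrollment gaps, public-plan coverage), independent
# constant-hazard endpoint processes with multiplicative policy effects in the
# policy year, and a post-policy switch wave to biosimilar product.
#
# All parameter defaults are stand-ins calibrated to the published cohort
# structure (cohort sizes ~1,800-2,400, ages 4-90 with mean ~43, ~54% male,
# ~92% switch uptake); no generative parameters for the real data exist.

#' Scenario configuration for the synthetic-claims generator
#'
#' @param seed Integer seed; fixes all randomness of [simulate_claims()].
#' @param cohort_years Integer vector of cohort years; the highest year is the
#'   policy year (default 2016:2019).
#' @param patients_per_year Number of originator-infliximab users generated per
#'   cohort year; scalar or one value per year. With default attrition the
#'   final cohorts land around 1,800-2,000 patients.
#' @param age_mean,age_sd,age_range Age-at-index distribution: normal
#'   truncated to `age_range` (years).
#' @param male_fraction Probability that a patient is male.
#' @param dispensation_interval_days Mean and SD (length-2 vector) of the gap
#'   between infliximab dispensations; gaps are floored at `min_interval_days`.
#' @param min_interval_days Minimum dispensation gap in days.
#' @param cycle_dose_range Range (mg) from which each patient's per-cycle
#'   infliximab dose is drawn (multiples of 50 mg).
#' @param days_supply Days of supply recorded on each infliximab dispensation.
#' @param ibd_met_prob Probability that a user carries the claims markers of
#'   the IBD case-finding algorithm (gastroenterologist prescriber,
#'   pre-index gastroenterology visits, IBD-flagged records).
#' @param gastro_prescriber_prob Probability (given IBD markers) that the
#'   patient's infliximab prescriber is a gastroenterologist.
#' @param discontinue_prob Probability that a user stops infliximab during the
#'   identification window (excluded as discontinuer).
#' @param pre_switch_prob Probability that a user switches to biosimilar
#'   before the index date (excluded as switcher).
#' @param no_enrollment_prob Probability that health-plan enrollment ends
#'   before the index date.
#' @param pharmacare_coverage_prob Probability that a patient's dispensations
#'   are accepted by the public drug plan. Scalar, one value per cohort year,
#'   or `NULL` for the default declining-coverage ramp (0.97 oldest year to
#'   0.90 policy year, mirroring the rising "No PharmaCare" exclusions in the
#'   source setting).
#' @param baseline_hazards Named vector of constant daily event hazards for
#'   the endpoint processes: `dose_escalation`, `other_biologic`,
#'   `antibiotic`, `new_prednisone`, `gastroenterologist_visit`,
#'   `physician_visit` (non-gastroenterology outpatient process), `ed_visit`,
#'   `emergency_admission`, `elective_admission`.
#' @param policy_effects Named vector of multiplicative hazard ratios applied
#'   to the policy-year cohort only (same names as `baseline_hazards`).
#' @param switch_compliance Fraction of policy-cohort users who switch to the
#'   biosimilar during the transition period.
#' @param transition_days Length of the transition period (days after index)
#'   over which switch times are uniform.
#' @param switch_back_prob Probability that a switcher later returns to the
#'   originator product.
#' @param prevalent_biosimilar_fraction Extra biosimilar-only (adult)
#'   users added per year, as a fraction of `patients_per_year`; these provide
#'   the pre-policy biosimilar market share and never enter the cohorts.
#' @param escalation_dose_factor Dose multiplier applied at an injected dose
#'   escalation event (default 1.3, above the 1.25 detection ratio).
#' @param mean_los_days Mean hospital length of stay (days).
#'
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(
    seed = 1L,
    cohort_years = 2016:2019,
    patients_per_year = 2400,
    age_mean = 43, age_sd = 17, age_range = c(4, 90),
    male_fraction = 0.54,
    dispensation_interval_days = c(56, 7),
    min_interval_days = 28,
    cycle_dose_range = c(300, 500),
    days_supply = 56L,
    ibd_met_prob = 0.90,
    gastro_prescriber_prob = 0.95,
    discontinue_prob = 0.035,
    pre_switch_prob = 0.008,
    no_enrollment_prob = 0.007,
    pharmacare_coverage_prob = NULL,
    baseline_hazards = c(
      dose_escalation = 0.001668,
      other_biologic = 7e-05,
      antibiotic = 3.5e-04,
      new_prednisone = 3.8e-04,
      gastroenterologist_visit = 0.00251,
      physician_visit = 0.05,
      ed_visit = 6.1e-04,
      emergency_admission = 2.0e-04,
      elective_admission = 2.0e-04
    ),
    policy_effects = c(
      dose_escalation = 1.58,
      other_biologic = 1.4,
      antibiotic = 0.8,
      new_prednisone = 0.8,
      gastroenterologist_visit = 1.95,
      physician_visit = 1.0,
      ed_visit = 1.0,
      emergency_admission = 0.6,
      elective_admission = 0.85
    ),
    switch_compliance = 0.92,
    transition_days = 182L,
    switch_back_prob = 0.007,
    prevalent_biosimilar_fraction = 0.10,
    escalation_dose_factor = 1.3,
    mean_los_days = 5) {

  cfg <- list(
    seed = seed, cohort_years = sort(unique(as.integer(cohort_years))),
    patients_per_year = patients_per_year,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    male_fraction = male_fraction,
    dispensation_interval_days = dispensation_interval_days,
    min_interval_days = min_interval_days,
    cycle_dose_range = cycle_dose_range, days_supply = as.integer(days_supply),
    ibd_met_prob = ibd_met_prob,
    gastro_prescriber_prob = gastro_prescriber_prob,
    discontinue_prob = discontinue_prob, pre_switch_prob = pre_switch_prob,
    no_enrollment_prob = no_enrollment_prob,
    pharmacare_coverage_prob = pharmacare_coverage_prob,
    baseline_hazards = baseline_hazards, policy_effects = policy_effects,
    switch_compliance = switch_compliance,
    transition_days = as.integer(transition_days),
    switch_back_prob = switch_back_prob,
    prevalent_biosimilar_fraction = prevalent_biosimilar_fraction,
    escalation_dose_factor = escalation_dose_factor,
    mean_los_days = mean_los_days
  )
  validate_scenario_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

hazard_names <- c(
  "dose_escalation", "other_biologic", "antibiotic", "new_prednisone",
  "gastroenterologist_visit", "physician_visit", "ed_visit",
  "emergency_admission", "elective_admission"
)

validate_scenario_config <- function(cfg) {
  bad <- function(field, why) {
    stop_ss(sprintf("invalid scenario config field '%s': %s", field, why),
            "scenario_config_error")
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1)) {
      bad(field, "must be a probability in [0, 1]")
    }
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed) ||
      cfg$seed != as.integer(cfg$seed)) bad("seed", "must be a single integer")
  if (length(cfg$cohort_years) < 1) bad("cohort_years", "needs >= 1 year")
  n_years <- length(cfg$cohort_years)
  if (!length(cfg$patients_per_year) %in% c(1L, n_years) ||
      any(cfg$patients_per_year < 0)) {
    bad("patients_per_year", "must be a non-negative scalar or one per year")
  }
  for (f in c("male_fraction", "ibd_met_prob", "gastro_prescriber_prob",
              "discontinue_prob", "pre_switch_prob", "no_enrollment_prob",
              "switch_compliance", "switch_back_prob",
              "prevalent_biosimilar_fraction")) chk_prob(f)
  if (!is.null(cfg$pharmacare_coverage_prob)) {
    v <- cfg$pharmacare_coverage_prob
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1) ||
        !length(v) %in% c(1L, n_years)) {
      bad("pharmacare_coverage_prob",
          "must be probabilities in [0, 1], scalar or one per year")
    }
  }
  for (f in c("baseline_hazards", "policy_effects")) {
    v <- cfg[[f]]
    missing <- setdiff(hazard_names, names(v))
    if (length(missing) > 0) {
      bad(f, paste("missing named entries:", paste(missing, collapse = ", ")))
    }
    if (anyNA(v) || any(v < 0)) bad(f, "must be non-negative")
  }
  if (cfg$discontinue_prob + cfg$pre_switch_prob > 1) {
    bad("discontinue_prob", "discontinue_prob + pre_switch_prob must be <= 1")
  }
  if (cfg$transition_days < 1 || cfg$transition_days > 365) {
    bad("transition_days", "must be in 1..365")
  }
  invisible(cfg)
}

resolve_coverage <- function(cfg) {
  ny <- length(cfg$cohort_years)
  v <- cfg$pharmacare_coverage_prob
  if (is.null(v)) {
    v <- if (ny == 1) 0.9 else seq(0.97, 0.90, length.out = ny)
  }
  if (length(v) == 1) v <- rep(v, ny)
  stats::setNames(v, as.character(cfg$cohort_years))
}

resolve_ppy <- function(cfg) {
  v <- cfg$patients_per_year
  if (length(v) == 1) v <- rep(v, length(cfg$cohort_years))
  stats::setNames(as.integer(v), as.character(cfg$cohort_years))
}

index_date_of <- function(year) as.Date(sprintf("%d-09-05", year))
window_start_of <- function(year) as.Date(sprintf("%d-03-07", year))

# truncated-normal ages via inverse-cdf sampling
draw_ages <- function(n, mean, sd, range) {
  lo <- pnorm(range[1], mean, sd)
  hi <- pnorm(range[2], mean, sd)
  pmin(range[2], pmax(range[1], round(qnorm(runif(n, lo, hi), mean, sd))))
}

# first-event day under a constant daily hazard; Inf when hazard is zero
draw_event_day <- function(n, hazard) {
  if (hazard <= 0) return(rep(Inf, n))
  ceiling(rexp(n, rate = hazard))
}

# Poisson-process event offsets on half-open day ranges. Returns a tibble of
# (idx, offset): offsets in 0..364 for follow-up, -365..-1 for the prior year.
draw_process <- function(n, rate, follow_up = TRUE) {
  if (rate <= 0) return(tibble::tibble(idx = integer(0), offset = integer(0)))
  counts <- rpois(n, 365 * rate)
  tot <- sum(counts)
  if (tot == 0) return(tibble::tibble(idx = integer(0), offset = integer(0)))
  day <- ceiling(runif(tot, 0, 365))  # day 1..365
  off <- if (follow_up) as.integer(day - 1L) else as.integer(-day)
  tibble::tibble(idx = rep(seq_len(n), counts), offset = off)
}

#' Generate a synthetic claims bundle
#'
#' Draws one wave of originator-infliximab users per cohort year, simulates
#' their dispensation cadence, attrition, endpoint event processes (with
#' policy effects in the policy year), health-plan enrollment and the
#' post-policy biosimilar switch wave, and returns the four claims tables.
#'
#' The same configuration and seed always yield an identical bundle. Per-year
#' generator bookkeeping is attached as `attr(bundle, "scenario_meta")`.
#'
#' @param config A [scenario_config()].
#' @return A `claims_bundle`.
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  set.seed(config$seed)
  years <- config$cohort_years
  policy_year <- max(years)
  ppy <- resolve_ppy(config)
  coverage <- resolve_coverage(config)

  parts <- lapply(years, function(y) {
    sim_year(config, y, ppy[[as.character(y)]], coverage[[as.character(y)]],
             is_policy = (y == policy_year))
  })

  bundle <- claims_bundle(
    enrollment = dplyr::bind_rows(lapply(parts, `[[`, "enrollment")),
    dispensations = dplyr::bind_rows(lapply(parts, `[[`, "dispensations")),
    visits = dplyr::bind_rows(lapply(parts, `[[`, "visits")),
    hospital = dplyr::bind_rows(lapply(parts, `[[`, "hospital")),
    validate = FALSE
  )
  attr(bundle, "scenario_meta") <- dplyr::bind_rows(lapply(parts, `[[`, "meta"))
  bundle
}

sim_year <- function(cfg, y, n, coverage_p, is_policy) {
  index <- index_date_of(y)
  gap_mean <- cfg$dispensation_interval_days[1]
  gap_sd <- cfg$dispensation_interval_days[2]
  supply <- cfg$days_supply
  hz <- cfg$baseline_hazards
  eff <- if (is_policy) cfg$policy_effects else
    stats::setNames(rep(1, length(hazard_names)), hazard_names)

  if (n == 0 && cfg$prevalent_biosimilar_fraction == 0) {
    return(list(enrollment = empty_table("enrollment"),
                dispensations = empty_table("dispensations"),
                visits = empty_table("visits"),
                hospital = empty_table("hospital"),
                meta = year_meta(y, 0L, logical(0), character(0), logical(0),
                                 logical(0))))
  }

  ids <- sprintf("Y%d-%05d", y, seq_len(n))
  age <- draw_ages(n, cfg$age_mean, cfg$age_sd, cfg$age_range)
  sex <- ifelse(runif(n) < cfg$male_fraction, "male", "female")
  birth_year <- y - age

  u <- runif(n)
  status <- ifelse(u < cfg$discontinue_prob, "discontinuer",
            ifelse(u < cfg$discontinue_prob + cfg$pre_switch_prob,
                   "pre_switcher", "continuing"))
  ibd_met <- runif(n) < cfg$ibd_met_prob
  covered <- runif(n) < coverage_p
  no_enroll <- runif(n) < cfg$no_enrollment_prob
  gastro_rx <- ibd_met & (runif(n) < cfg$gastro_prescriber_prob)
  base_q <- sample(seq(cfg$cycle_dose_range[1], cfg$cycle_dose_range[2],
                       by = 50), n, replace = TRUE)
  biosim_brand <- sample(c("Inflectra", "Renflexis"), n, replace = TRUE)

  # ---- infliximab cadence (integer day offsets relative to index = 0) ----
  # therapy history is capped at 360 days before index so that one year's
  # wave never dispenses inside an earlier year's identification window
  first_off <- -round(runif(n, 60, 360))
  first_off[status == "discontinuer"] <-
    -round(runif(sum(status == "discontinuer"), 250, 360))
  disc_anchor <- rep(NA_integer_, n)
  disc_anchor[status == "discontinuer"] <-
    -round(runif(sum(status == "discontinuer"), supply + 31, 175))
  presw_anchor <- rep(NA_integer_, n)
  presw_anchor[status == "pre_switcher"] <-
    -round(runif(sum(status == "pre_switcher"), 40, 70))
  cadence_end <- rep(364L, n)
  cadence_end[status == "discontinuer"] <-
    disc_anchor[status == "discontinuer"] - cfg$min_interval_days
  cadence_end[status == "pre_switcher"] <-
    presw_anchor[status == "pre_switcher"] - cfg$min_interval_days

  K <- ceiling((360 + 365) / cfg$min_interval_days) + 2L
  gaps <- matrix(pmax(cfg$min_interval_days, round(rnorm(n * K, gap_mean, gap_sd))),
                 nrow = K, ncol = n)
  for (k in 2:K) gaps[k, ] <- gaps[k - 1L, ] + gaps[k, ]
  offm <- rbind(first_off, gaps + matrix(first_off, K, n, byrow = TRUE))
  capm <- matrix(cadence_end, K + 1L, n, byrow = TRUE)
  keep <- offm <= capm
  inflx <- tibble::tibble(
    idx = rep(seq_len(n), each = K + 1L)[keep],
    offset = as.integer(offm[keep])
  )
  # anchor dispensations: last in-window dispensation of discontinuers (too
  # early to cover the index date) and last originator of pre-index switchers
  anchors <- tibble::tibble(
    idx = which(!is.na(disc_anchor) | !is.na(presw_anchor)),
    offset = as.integer(ifelse(is.na(disc_anchor), presw_anchor,
                               disc_anchor)[!is.na(disc_anchor) |
                                            !is.na(presw_anchor)])
  )
  inflx <- dplyr::bind_rows(inflx, anchors)

  # ---- policy-year switch wave ----
  switch_off <- rep(Inf, n)
  back_off <- rep(Inf, n)
  if (is_policy) {
    eligible <- status == "continuing"
    compliant <- eligible & (runif(n) < cfg$switch_compliance)
    switch_off[compliant] <- floor(runif(sum(compliant), 0, cfg$transition_days))
    back <- compliant & (runif(n) < cfg$switch_back_prob)
    back_off[back] <- switch_off[back] + round(runif(sum(back), 30, 120))
  }

  # ---- injected endpoint events ----
  esc_day <- draw_event_day(n, hz[["dose_escalation"]] * eff[["dose_escalation"]])
  esc_day[status != "continuing"] <- Inf
  abx_day <- draw_event_day(n, hz[["antibiotic"]] * eff[["antibiotic"]])
  pred_day <- draw_event_day(n, hz[["new_prednisone"]] * eff[["new_prednisone"]])
  bio_day <- draw_event_day(n, hz[["other_biologic"]] * eff[["other_biologic"]])

  esc_idx <- which(esc_day <= 365)
  esc_rows <- tibble::tibble(idx = esc_idx,
                             offset = as.integer(esc_day[esc_idx] - 1L))

  inflx_all <- dplyr::bind_rows(
    dplyr::mutate(inflx, escalated = FALSE),
    dplyr::mutate(esc_rows, escalated = TRUE)
  )
  cls <- ifelse(inflx_all$offset >= back_off[inflx_all$idx], "originator_infliximab",
         ifelse(inflx_all$offset >= switch_off[inflx_all$idx],
                "biosimilar_infliximab", "originator_infliximab"))
  qty <- ifelse(inflx_all$escalated,
                round(base_q[inflx_all$idx] * cfg$escalation_dose_factor),
                base_q[inflx_all$idx])

  disp_inflx <- tibble::tibble(
    patient_id = ids[inflx_all$idx],
    service_date = index + inflx_all$offset,
    drug_class = cls,
    brand = ifelse(cls == "originator_infliximab", "Remicade",
                   biosim_brand[inflx_all$idx]),
    quantity_mg = as.double(qty),
    days_supply = supply,
    prescriber_specialty = ifelse(gastro_rx[inflx_all$idx],
                                  "gastroenterology", "other"),
    payer_accepted = covered[inflx_all$idx]
  )

  event_disp <- function(day, class, brand, quantity, dsupply) {
    i <- which(day <= 365)
    tibble::tibble(
      patient_id = ids[i],
      service_date = index + as.integer(day[i] - 1L),
      drug_class = class, brand = brand, quantity_mg = quantity,
      days_supply = as.integer(dsupply),
      prescriber_specialty = ifelse(gastro_rx[i], "gastroenterology", "other"),
      payer_accepted = covered[i]
    )
  }
  disp_events <- dplyr::bind_rows(
    event_disp(abx_day, "antibiotic_ibd", "ciprofloxacin", 7000, 14L),
    event_disp(pred_day, "prednisone", "prednisone", 1200, 30L),
    event_disp(bio_day, "other_biologic", "adalimumab", 80, 14L)
  )

  # pre-index switchers: biosimilar cadence from shortly after their last
  # originator dispensation (this is what triggers the switcher exclusion)
  pw <- which(status == "pre_switcher")
  if (length(pw) > 0) {
    b_start <- presw_anchor[pw] + round(runif(length(pw), 10, 25))
    b_count <- pmax(1L, floor((364 - b_start) / gap_mean) + 1L)
    presw_bio <- tibble::tibble(
      patient_id = rep(ids[pw], b_count),
      service_date = index + rep(b_start, b_count) +
        (sequence(b_count) - 1L) * as.integer(gap_mean),
      drug_class = "biosimilar_infliximab",
      brand = rep(biosim_brand[pw], b_count),
      quantity_mg = as.double(rep(base_q[pw], b_count)),
      days_supply = supply,
      prescriber_specialty = rep(ifelse(gastro_rx[pw], "gastroenterology",
                                        "other"), b_count),
      payer_accepted = rep(covered[pw], b_count)
    )
    disp_events <- dplyr::bind_rows(disp_events, presw_bio)
  }

  # ---- prevalent biosimilar-only users (adults; background market share) ----
  m <- round(n * cfg$prevalent_biosimilar_fraction)
  if (m > 0) {
    pids <- sprintf("Y%d-B%04d", y, seq_len(m))
    page <- draw_ages(m, cfg$age_mean, cfg$age_sd, c(18, cfg$age_range[2]))
    pstart <- -round(runif(m, 300, 600))
    pcount <- floor((364 - pstart) / gap_mean) + 1L
    prev_disp <- tibble::tibble(
      patient_id = rep(pids, pcount),
      service_date = index + rep(pstart, pcount) +
        (sequence(pcount) - 1L) * as.integer(gap_mean),
      drug_class = "biosimilar_infliximab",
      brand = rep(sample(c("Inflectra", "Renflexis"), m, replace = TRUE), pcount),
      quantity_mg = as.double(rep(sample(seq(cfg$cycle_dose_range[1],
                                             cfg$cycle_dose_range[2], by = 50),
                                         m, replace = TRUE), pcount)),
      days_supply = supply,
      prescriber_specialty = "gastroenterology",
      payer_accepted = TRUE
    )
    prev_enr <- tibble::tibble(
      patient_id = pids,
      start_date = index - round(runif(m, 800, 1600)),
      end_date = index + 364L,
      birth_year = as.integer(y - page),
      sex = ifelse(runif(m) < cfg$male_fraction, "male", "female")
    )
  } else {
    prev_disp <- NULL
    prev_enr <- NULL
  }

  dispensations <- dplyr::bind_rows(disp_inflx, disp_events, prev_disp) |>
    dplyr::arrange(.data$patient_id, .data$service_date, .data$drug_class)

  # ---- enrollment ----
  enr_end <- rep(index + 364L, n)
  enr_end[no_enroll] <- index - round(runif(sum(no_enroll), 10, 120))
  enrollment <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = ids,
      start_date = index - round(runif(n, 800, 1600)),
      end_date = enr_end,
      birth_year = as.integer(birth_year),
      sex = sex
    ),
    prev_enr
  )

  # ---- outpatient / ED visit processes ----
  r_gas <- hz[["gastroenterologist_visit"]]
  r_oth <- hz[["physician_visit"]]
  r_ed <- hz[["ed_visit"]]
  gas_pre <- draw_process(n, r_gas, follow_up = FALSE)
  gas_pre <- gas_pre[ibd_met[gas_pre$idx], ]  # IBD-negative users lack them
  gas_post <- draw_process(n, r_gas * eff[["gastroenterologist_visit"]])
  oth_pre <- draw_process(n, r_oth, follow_up = FALSE)
  oth_post <- draw_process(n, r_oth * eff[["physician_visit"]])
  ed_pre <- draw_process(n, r_ed, follow_up = FALSE)
  ed_post <- draw_process(n, r_ed * eff[["ed_visit"]])

  visit_rows <- function(ev, specialty, setting, flag_p) {
    k <- nrow(ev)
    if (k == 0) return(NULL)
    tibble::tibble(
      patient_id = ids[ev$idx],
      service_date = index + ev$offset,
      provider_type = ifelse(specialty == "other" & setting == "outpatient" &
                               runif(k) < 0.15, "nurse_practitioner", "physician"),
      specialty = specialty,
      setting = setting,
      diagnosis_flag_ibd = ibd_met[ev$idx] & (runif(k) < flag_p)
    )
  }
  visits <- dplyr::bind_rows(
    visit_rows(dplyr::bind_rows(gas_pre, gas_post), "gastroenterology",
               "outpatient", 0.4),
    visit_rows(dplyr::bind_rows(oth_pre, oth_post), "other", "outpatient", 0.1),
    visit_rows(dplyr::bind_rows(ed_pre, ed_post), "other",
               "emergency_department", 0.2)
  )
  if (is.null(visits)) visits <- empty_table("visits")
  visits <- dplyr::arrange(visits, .data$patient_id, .data$service_date)

  # ---- hospital stays ----
  stay_rows <- function(ev, category) {
    k <- nrow(ev)
    if (k == 0) return(NULL)
    los <- rpois(k, max(cfg$mean_los_days - 1, 0)) + 1L
    tibble::tibble(
      patient_id = ids[ev$idx],
      admission_date = index + ev$offset,
      discharge_date = index + ev$offset + los,
      admission_category = category,
      diagnosis_flag_ibd = ibd_met[ev$idx] & (runif(k) < 0.5)
    )
  }
  hospital <- dplyr::bind_rows(
    stay_rows(dplyr::bind_rows(
      draw_process(n, hz[["emergency_admission"]], follow_up = FALSE),
      draw_process(n, hz[["emergency_admission"]] * eff[["emergency_admission"]])
    ), "emergency"),
    stay_rows(dplyr::bind_rows(
      draw_process(n, hz[["elective_admission"]], follow_up = FALSE),
      draw_process(n, hz[["elective_admission"]] * eff[["elective_admission"]])
    ), "elective")
  )
  if (is.null(hospital)) hospital <- empty_table("hospital")
  hospital <- dplyr::arrange(hospital, .data$patient_id, .data$admission_date)

  list(
    enrollment = enrollment,
    dispensations = dispensations,
    visits = visits,
    hospital = hospital,
    meta = year_meta(y, n, ibd_met, status, no_enroll, covered)
  )
}

year_meta <- function(y, n, ibd_met, status, no_enroll, covered) {
  tibble::tibble(
    year = y,
    n_users_simulated = n,
    n_ibd_markers = sum(ibd_met),
    n_discontinuers = sum(status == "discontinuer"),
    n_pre_switchers = sum(status == "pre_switcher"),
    n_no_enrollment = sum(no_enroll),
    n_uncovered = sum(!covered)
  )
}

#' Closed-form cumulative incidence implied by a scenario
#'
#' For endpoints generated by a constant-hazard process, returns
#' `100 * (1 - exp(-h * day))`, the analytic target the simulated pipeline
#' must reproduce. Supported endpoints: `dose_escalation`, `other_biologic`,
#' `antibiotic`, `new_prednisone`, `gastroenterologist_visit`, `ed_visit`,
#' `emergency_admission`, and `physician_visit_1` (whose effective hazard is
#' the sum of the gastroenterology and other-outpatient process rates).
#'
#' @param config A [scenario_config()].
#' @param endpoint Endpoint name (see [endpoint_catalog()]).
#' @param day Follow-up day(s), 1..365.
#' @param cohort `"historical"` (baseline hazards) or `"policy"` (hazards
#'   multiplied by the configured policy effects).
#' @return Cumulative incidence in percent.
#' @export
expected_cumulative_incidence <- function(config, endpoint, day,
                                          cohort = c("historical", "policy")) {
  stopifnot(inherits(config, "scenario_config"))
  cohort <- match.arg(cohort)
  hz <- config$baseline_hazards
  pe <- if (cohort == "policy") config$policy_effects else
    stats::setNames(rep(1, length(hazard_names)), hazard_names)
  h <- switch(endpoint,
    dose_escalation = hz[["dose_escalation"]] * pe[["dose_escalation"]],
    other_biologic = hz[["other_biologic"]] * pe[["other_biologic"]],
    antibiotic = hz[["antibiotic"]] * pe[["antibiotic"]],
    new_prednisone = hz[["new_prednisone"]] * pe[["new_prednisone"]],
    gastroenterologist_visit = hz[["gastroenterologist_visit"]] *
      pe[["gastroenterologist_visit"]],
    ed_visit = hz[["ed_visit"]] * pe[["ed_visit"]],
    emergency_admission = hz[["emergency_admission"]] *
      pe[["emergency_admission"]],
    physician_visit_1 = hz[["physician_visit"]] * pe[["physician_visit"]] +
      hz[["gastroenterologist_visit"]] * pe[["gastroenterologist_visit"]],
    stop_ss(sprintf("endpoint '%s' has no constant-hazard closed form",
                    endpoint), "unsupported_endpoint")
  )
  if (any(day < 1 | day > 365)) {
    stop_ss("day must be within 1..365", "invalid_argument")
  }
  100 * (1 - exp(-h * day))
}
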