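# Endpoint ascertainment: for every cohort member, the follow-up day
# (1..365, day 1 = index date) of each medication and health-service
# endpoint, or NA when the endpoint did not occur within follow-up.

#' Catalog of monitored endpoints
#'
#' @return A tibble with columns `name`, `label` and `group`
#'   (medication / health_service) for the 16 monitored endpoints.
#' @export
endpoint_catalog <- function() {
  tibble::tribble(
    ~name, ~label, ~group,
    "infliximab_disp_1", "1st infliximab dispensation", "medication",
    "infliximab_disp_2", "2nd infliximab dispensation", "medication",
    "infliximab_disp_3", "3rd infliximab dispensation", "medication",
    "infliximab_disp_4", "4th infliximab dispensation", "medication",
    "dose_escalation", "Infliximab dose escalation (>= 25%)", "medication",
    "other_biologic", "Switch to a different biologic", "medication",
    "antibiotic", "IBD-related antibiotic dispensation", "medication",
    "new_prednisone", "New use of prednisone", "medication",
    "physician_visit_1", "1st physician/NP outpatient visit", "health_service",
    "physician_visit_2", "2nd physician/NP outpatient visit", "health_service",
    "physician_visit_3", "3rd physician/NP outpatient visit", "health_service",
    "physician_visit_4", "4th physician/NP outpatient visit", "health_service",
    "gastroenterologist_visit", "1st gastroenterologist visit", "health_service",
    "ed_visit", "1st emergency department visit", "health_service",
    "hospital_discharge", "1st discharge from hospital", "health_service",
    "emergency_admission", "1st emergency admission", "health_service"
  )
}

# assemble an event-time table over the cohort membership
event_time_table <- function(cohort, event_days, endpoint,
                             extra = NULL) {
  out <- tibble::tibble(patient_id = cohort$members)
  out <- dplyr::left_join(out, event_days, by = "patient_id")
  if (!"event_day" %in% names(out)) out$event_day <- NA_integer_
  out$event_day <- as.integer(out$event_day)
  if (!is.null(extra)) out <- dplyr::left_join(out, extra, by = "patient_id")
  structure(out, endpoint = endpoint, n = length(cohort$members),
            class = c("event_time_table", class(out)))
}

# follow-up day of a date vector relative to a cohort definition; NA outside
fup_day <- function(dates, definition) {
  d <- follow_up_day(dates, definition$index_date)
  d[d < 1L | d > definition$follow_up_days] <- NA_integer_
  d
}

# day of the n-th distinct event day per patient
nth_day <- function(events, n) {
  events |>
    dplyr::distinct(.data$patient_id, .data$day) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(event_day = sort(.data$day)[n], .groups = "drop") |>
    dplyr::filter(!is.na(.data$event_day))
}

#' Day of the n-th infliximab dispensation during follow-up
#'
#' Counts distinct service dates with a dispensation of either infliximab
#' product (originator or biosimilar) on or after the index date; same-day
#' records collapse to a single event.
#'
#' @param bundle A `claims_bundle`.
#' @param cohort A `cohort`.
#' @param n Which dispensation (1..4).
#' @return An `event_time_table` (tibble of `patient_id`, `event_day`).
#' @export
nth_infliximab_dispensation <- function(bundle, cohort, n) {
  stopifnot(n >= 1, n <= 4)
  def <- cohort$definition
  dp <- bundle$dispensations
  ev <- dp[dp$patient_id %in% cohort$members &
             dp$drug_class %in% c("originator_infliximab",
                                  "biosimilar_infliximab"), ]
  ev$day <- fup_day(ev$service_date, def)
  ev <- ev[!is.na(ev$day), c("patient_id", "day")]
  event_time_table(cohort, nth_day(ev, n),
                   paste0("infliximab_disp_", n))
}

#' Day of the first infliximab dose escalation
#'
#' A dose escalation is the first follow-up dispensation whose total daily
#' dose (mg of infliximab per day of supply, summed over same-day records) is
#' at least `ratio` times the mean daily dose of all earlier dispensations on
#' record, pre-index dispensations included. Patients whose first-ever
#' infliximab dispensation falls in follow-up can never escalate (no
#' baseline). The product in use at the first escalation is reported in the
#' `product` column.
#'
#' @param bundle A `claims_bundle`.
#' @param cohort A `cohort`.
#' @param ratio Escalation threshold on the daily-dose ratio (default 1.25,
#'   inclusive).
#' @param lookback_days Restrict the baseline average to dispensations within
#'   this many days before the current one (default `Inf`: all earlier
#'   dispensations).
#' @return An `event_time_table` with columns `patient_id`, `event_day`,
#'   `product`.
#' @export
dose_escalation <- function(bundle, cohort, ratio = 1.25,
                            lookback_days = Inf) {
  def <- cohort$definition
  dp <- bundle$dispensations
  dp <- dp[dp$patient_id %in% cohort$members &
             dp$drug_class %in% c("originator_infliximab",
                                  "biosimilar_infliximab"), ]
  daily <- dp |>
    dplyr::group_by(.data$patient_id, .data$service_date) |>
    dplyr::summarise(
      daily_dose = sum(.data$quantity_mg / .data$days_supply),
      product = if (any(.data$drug_class == "originator_infliximab"))
        "originator_infliximab" else "biosimilar_infliximab",
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient_id, .data$service_date)

  if (is.infinite(lookback_days)) {
    daily <- daily |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(
        prior_mean = dplyr::lag(cumsum(.data$daily_dose) /
                                  dplyr::row_number())
      ) |>
      dplyr::ungroup()
  } else {
    daily <- daily |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(prior_mean = vapply(seq_along(.data$daily_dose), function(i) {
        win <- .data$service_date < .data$service_date[i] &
          .data$service_date >= .data$service_date[i] - lookback_days
        if (!any(win)) NA_real_ else mean(.data$daily_dose[win])
      }, numeric(1))) |>
      dplyr::ungroup()
  }

  daily$day <- fup_day(daily$service_date, def)
  hits <- daily[!is.na(daily$day) & !is.na(daily$prior_mean) &
                  daily$daily_dose >= ratio * daily$prior_mean * (1 - 1e-9), ]
  first_hit <- hits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  event_time_table(
    cohort,
    first_hit[, c("patient_id", "day")] |> dplyr::rename(event_day = "day"),
    "dose_escalation",
    extra = first_hit[, c("patient_id", "product")]
  )
}

first_dispensation_day <- function(bundle, cohort, classes, endpoint) {
  def <- cohort$definition
  dp <- bundle$dispensations
  ev <- dp[dp$patient_id %in% cohort$members & dp$drug_class %in% classes, ]
  ev$day <- fup_day(ev$service_date, def)
  ev <- ev[!is.na(ev$day), c("patient_id", "day")]
  event_time_table(cohort, nth_day(ev, 1L), endpoint)
}

#' Day of the first dispensation of a different biologic
#' @inheritParams nth_infliximab_dispensation
#' @return An `event_time_table`.
#' @export
switch_to_other_biologic <- function(bundle, cohort) {
  first_dispensation_day(bundle, cohort, "other_biologic", "other_biologic")
}

#' Day of the first IBD-related antibiotic dispensation
#' @inheritParams nth_infliximab_dispensation
#' @return An `event_time_table`.
#' @export
antibiotic_dispensation <- function(bundle, cohort) {
  first_dispensation_day(bundle, cohort, "antibiotic_ibd", "antibiotic")
}

#' Day of the first new use of prednisone
#'
#' A prednisone dispensation qualifies as new use when no systemic
#' corticosteroid supply interval (`[service_date, service_date +
#' days_supply)`, prednisone included) intersects the `washout_days` days
#' before it.
#'
#' @inheritParams nth_infliximab_dispensation
#' @param washout_days Corticosteroid-free washout window (default 183,
#'   i.e. six months).
#' @return An `event_time_table`.
#' @export
new_prednisone_use <- function(bundle, cohort, washout_days = 183L) {
  def <- cohort$definition
  dp <- bundle$dispensations[bundle$dispensations$patient_id %in%
                               cohort$members, ]
  cort <- dp[dp$drug_class %in% c("prednisone",
                                  "other_systemic_corticosteroid"), ]
  pred <- cort[cort$drug_class == "prednisone", ]
  pred$day <- fup_day(pred$service_date, def)
  pred <- pred[!is.na(pred$day), c("patient_id", "service_date", "day")]
  if (nrow(pred) == 0) {
    return(event_time_table(cohort,
                            tibble::tibble(patient_id = character(0),
                                           event_day = integer(0)),
                            "new_prednisone"))
  }
  prior <- dplyr::inner_join(
    pred,
    cort[, c("patient_id", "service_date", "days_supply")] |>
      dplyr::rename(cort_date = "service_date"),
    by = "patient_id", relationship = "many-to-many"
  ) |>
    dplyr::filter(
      .data$cort_date <= .data$service_date - 1L,
      .data$cort_date + .data$days_supply - 1L >=
        .data$service_date - washout_days
    ) |>
    dplyr::distinct(.data$patient_id, .data$service_date)
  qualifying <- dplyr::anti_join(pred, prior,
                                 by = c("patient_id", "service_date"))
  event_time_table(cohort, nth_day(qualifying[, c("patient_id", "day")], 1L),
                   "new_prednisone")
}

#' Day of the n-th health-service event
#'
#' @inheritParams nth_infliximab_dispensation
#' @param kind One of `physician_visit` (outpatient visit to a physician of
#'   any specialty or a nurse practitioner), `gastroenterologist_visit`,
#'   `ed_visit`, `hospital_discharge` (event day is the discharge date, any
#'   admission category), `emergency_admission` (event day is the admission
#'   date of an emergency-category stay).
#' @param n Which event (1..4 for `physician_visit`, 1 otherwise).
#' @return An `event_time_table`.
#' @export
health_service_events <- function(bundle, cohort, kind, n = 1L) {
  kinds <- c("physician_visit", "gastroenterologist_visit", "ed_visit",
             "hospital_discharge", "emergency_admission")
  if (!kind %in% kinds) {
    stop_ss(sprintf("unknown health-service kind '%s'", kind),
            "invalid_argument")
  }
  if (kind != "physician_visit" && n != 1L) {
    stop_ss("n > 1 is only supported for physician_visit", "invalid_argument")
  }
  def <- cohort$definition
  vs <- bundle$visits[bundle$visits$patient_id %in% cohort$members, ]
  hs <- bundle$hospital[bundle$hospital$patient_id %in% cohort$members, ]
  ev <- switch(kind,
    physician_visit = {
      v <- vs[vs$setting == "outpatient", ]
      tibble::tibble(patient_id = v$patient_id,
                     day = fup_day(v$service_date, def))
    },
    gastroenterologist_visit = {
      v <- vs[vs$setting == "outpatient" &
                vs$specialty == "gastroenterology", ]
      tibble::tibble(patient_id = v$patient_id,
                     day = fup_day(v$service_date, def))
    },
    ed_visit = {
      v <- vs[vs$setting == "emergency_department", ]
      tibble::tibble(patient_id = v$patient_id,
                     day = fup_day(v$service_date, def))
    },
    hospital_discharge = tibble::tibble(
      patient_id = hs$patient_id,
      day = fup_day(hs$discharge_date, def)
    ),
    emergency_admission = {
      h <- hs[hs$admission_category == "emergency", ]
      tibble::tibble(patient_id = h$patient_id,
                     day = fup_day(h$admission_date, def))
    }
  )
  ev <- ev[!is.na(ev$day), ]
  name <- if (kind == "physician_visit") paste0("physician_visit_", n) else kind
  event_time_table(cohort, nth_day(ev, as.integer(n)), name)
}

#' Ascertain every monitored endpoint for a cohort
#'
#' @inheritParams nth_infliximab_dispensation
#' @param endpoints Endpoint names (default: all of [endpoint_catalog()]).
#' @return A named list of `event_time_table`s.
#' @export
ascertain_endpoints <- function(bundle, cohort,
                                endpoints = endpoint_catalog()$name) {
  out <- lapply(endpoints, function(ep) {
    if (grepl("^infliximab_disp_", ep)) {
      nth_infliximab_dispensation(bundle, cohort,
                                  as.integer(sub("^infliximab_disp_", "", ep)))
    } else if (ep == "dose_escalation") {
      dose_escalation(bundle, cohort)
    } else if (ep == "other_biologic") {
      switch_to_other_biologic(bundle, cohort)
    } else if (ep == "antibiotic") {
      antibiotic_dispensation(bundle, cohort)
    } else if (ep == "new_prednisone") {
      new_prednisone_use(bundle, cohort)
    } else if (grepl("^physician_visit_", ep)) {
      health_service_events(bundle, cohort, "physician_visit",
                            as.integer(sub("^physician_visit_", "", ep)))
    } else {
      health_service_events(bundle, cohort, ep)
    }
  })
  names(out) <- endpoints
  out
}

#' Daily biosimilar switch and switch-back curves for the policy cohort
#'
#' A patient has switched on the day of their first biosimilar dispensation
#' on or after index, and switched back on the day of a subsequent originator
#' dispensation. Curves are cumulative percentages with fixed denominators:
#' cohort members for switching, switchers (by day 365) for switching back.
#' Strata: all members, adults (age >= 18 at index) and pediatric patients.
#'
#' @inheritParams nth_infliximab_dispensation
#' @return A tibble with columns `stratum`, `day`, `n`, `n_switched`,
#'   `pct_switched`, `pct_switched_back`; summary percentages are attached as
#'   attributes `uptake_pct` and `switch_back_pct` (share of switchers, all
#'   strata combined).
#' @export
biosimilar_switch_curve <- function(bundle, cohort) {
  def <- cohort$definition
  dp <- bundle$dispensations[bundle$dispensations$patient_id %in%
                               cohort$members, ]
  dp$day <- fup_day(dp$service_date, def)
  dp <- dp[!is.na(dp$day), ]
  bio <- dp[dp$drug_class == "biosimilar_infliximab", ]
  first_bio <- if (nrow(bio) == 0) {
    tibble::tibble(patient_id = character(0), switch_day = integer(0))
  } else {
    dplyr::group_by(bio, .data$patient_id) |>
      dplyr::summarise(switch_day = min(.data$day), .groups = "drop")
  }
  back_cand <- dplyr::inner_join(
    dp[dp$drug_class == "originator_infliximab", c("patient_id", "day")],
    first_bio, by = "patient_id"
  ) |>
    dplyr::filter(.data$day > .data$switch_day)
  back <- if (nrow(back_cand) == 0) {
    tibble::tibble(patient_id = character(0), back_day = integer(0))
  } else {
    dplyr::group_by(back_cand, .data$patient_id) |>
      dplyr::summarise(back_day = min(.data$day), .groups = "drop")
  }

  en <- bundle$enrollment |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  age <- en$birth_year[match(cohort$members, en$patient_id)]
  age <- def$year - age
  members <- tibble::tibble(
    patient_id = cohort$members,
    adult = !is.na(age) & age >= 18
  ) |>
    dplyr::left_join(first_bio, by = "patient_id") |>
    dplyr::left_join(back, by = "patient_id")

  strata <- list(all = members, adult = members[members$adult, ],
                 pediatric = members[!members$adult, ])
  days <- seq_len(def$follow_up_days)
  curves <- dplyr::bind_rows(lapply(names(strata), function(s) {
    mm <- strata[[s]]
    n_str <- nrow(mm)
    n_sw <- sum(!is.na(mm$switch_day))
    sw <- tabulate(mm$switch_day[!is.na(mm$switch_day)],
                   nbins = def$follow_up_days)
    bk <- tabulate(mm$back_day[!is.na(mm$back_day)],
                   nbins = def$follow_up_days)
    pct_sw <- if (n_str > 0) 100 * cumsum(sw) / n_str else rep(NA_real_, length(days))
    pct_bk <- if (n_sw > 0) 100 * cumsum(bk) / n_sw else rep(NA_real_, length(days))
    tibble::tibble(
      stratum = s, day = days, n = n_str, n_switched = n_sw,
      pct_switched = pct_sw, pct_switched_back = pct_bk
    )
  }))
  all_rows <- curves[curves$stratum == "all", ]
  structure(curves,
            uptake_pct = all_rows$pct_switched[def$follow_up_days],
            switch_back_pct = all_rows$pct_switched_back[def$follow_up_days])
}
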