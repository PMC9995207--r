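# Cohort construction: one policy cohort and historical comparator cohorts of
# prevalent originator-infliximab users with IBD, assembled with a fixed
# inclusion/exclusion ladder and full patient-flow accounting.

#' Cohort definition for a given year
#'
#' The identification window runs from March 7 to September 4 of the cohort
#' year; the index date is September 5 and follow-up covers 365 days with
#' day 1 being the index date itself.
#'
#' @param year Cohort year (integer).
#' @return A `cohort_definition` list with `year`, `window_start`,
#'   `window_end`, `index_date` and `follow_up_days`.
#' @export
cohort_definition <- function(year) {
  year <- as.integer(year)
  structure(
    list(
      year = year,
      window_start = window_start_of(year),
      window_end = index_date_of(year) - 1L,
      index_date = index_date_of(year),
      follow_up_days = 365L
    ),
    class = "cohort_definition"
  )
}

#' Tunable cohort-building parameters
#'
#' Operationalizations of criteria whose exact ascertainment rules are not
#' observable in the abstracted data model; all are stand-ins with documented
#' defaults.
#'
#' @param gastro_visit_min Minimum number of gastroenterology outpatient
#'   visits in the lookback year that satisfies the IBD algorithm (default 2).
#' @param ibd_lookback_days Days before index searched for IBD markers
#'   (default 365).
#' @param grace_days Grace period added to the last in-window dispensation's
#'   days of supply when deciding whether a patient still used the originator
#'   on the index date (default 30).
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(gastro_visit_min = 2L, ibd_lookback_days = 365L,
                          grace_days = 30L) {
  structure(
    list(gastro_visit_min = as.integer(gastro_visit_min),
         ibd_lookback_days = as.integer(ibd_lookback_days),
         grace_days = as.integer(grace_days)),
    class = "cohort_params"
  )
}

#' Identify originator-infliximab users with IBD
#'
#' Candidates are patients with at least one originator-infliximab
#' dispensation dated inside the identification window who additionally meet
#' the IBD case-finding algorithm: an infliximab dispensation from a
#' gastroenterologist (on or before index), at least `gastro_visit_min`
#' gastroenterology outpatient visits in the lookback year, or any
#' IBD-flagged visit or hospital record in the lookback year.
#'
#' @param bundle A `claims_bundle`.
#' @param definition A [cohort_definition()].
#' @param params A [cohort_params()].
#' @return A `cohort_candidates` list: `patients` (character vector),
#'   `n_originator_users`, `n_with_ibd`.
#' @export
identify_ibd_originator_users <- function(bundle, definition,
                                          params = cohort_params()) {
  stopifnot(inherits(definition, "cohort_definition"))
  idx <- definition$index_date
  lb_start <- idx - params$ibd_lookback_days
  dp <- bundle$dispensations

  users <- unique(dp$patient_id[
    dp$drug_class == "originator_infliximab" &
      dp$service_date >= definition$window_start &
      dp$service_date <= definition$window_end
  ])

  crit_rx <- unique(dp$patient_id[
    dp$drug_class %in% c("originator_infliximab", "biosimilar_infliximab") &
      dp$prescriber_specialty == "gastroenterology" &
      dp$service_date <= idx
  ])

  vs <- bundle$visits
  gas <- vs[vs$specialty == "gastroenterology" & vs$setting == "outpatient" &
              vs$service_date >= lb_start & vs$service_date < idx, ]
  crit_visits <- gas |>
    dplyr::distinct(.data$patient_id, .data$service_date) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n >= params$gastro_visit_min) |>
    dplyr::pull(.data$patient_id)

  crit_dx <- unique(c(
    vs$patient_id[vs$diagnosis_flag_ibd & vs$service_date >= lb_start &
                    vs$service_date < idx],
    bundle$hospital$patient_id[
      bundle$hospital$diagnosis_flag_ibd &
        bundle$hospital$admission_date >= lb_start &
        bundle$hospital$admission_date < idx
    ]
  ))

  ibd <- union(crit_rx, union(crit_visits, crit_dx))
  candidates <- sort(intersect(users, ibd))
  structure(
    list(patients = candidates,
         n_originator_users = length(users),
         n_with_ibd = length(candidates)),
    class = "cohort_candidates"
  )
}

#' Patient-flow accounting for one cohort
#'
#' Reconciles inclusion and exclusion counts; the final cohort size is always
#' computed as `n_with_ibd` minus the four exclusion counts.
#'
#' @param n_originator_users Users of the originator in the window.
#' @param n_with_ibd Users also meeting the IBD algorithm.
#' @param excluded_discontinuers,excluded_switchers,excluded_no_enrollment,excluded_no_pharmacare
#'   Exclusion counts, each patient counted once at the first applicable
#'   criterion.
#' @return A `patient_flow` list including the derived `n_final`.
#' @export
patient_flow <- function(n_originator_users, n_with_ibd,
                         excluded_discontinuers, excluded_switchers,
                         excluded_no_enrollment, excluded_no_pharmacare) {
  counts <- c(n_originator_users, n_with_ibd, excluded_discontinuers,
              excluded_switchers, excluded_no_enrollment,
              excluded_no_pharmacare)
  if (anyNA(counts) || any(counts < 0)) {
    stop_ss("patient flow counts must be non-negative", "patient_flow_error")
  }
  n_final <- n_with_ibd - (excluded_discontinuers + excluded_switchers +
                             excluded_no_enrollment + excluded_no_pharmacare)
  if (n_final < 0) {
    stop_ss("exclusions exceed the number of IBD originator users",
            "patient_flow_error")
  }
  structure(
    list(n_originator_users = n_originator_users, n_with_ibd = n_with_ibd,
         excluded_discontinuers = excluded_discontinuers,
         excluded_switchers = excluded_switchers,
         excluded_no_enrollment = excluded_no_enrollment,
         excluded_no_pharmacare = excluded_no_pharmacare,
         n_final = n_final),
    class = "patient_flow"
  )
}

#' Apply the exclusion ladder to cohort candidates
#'
#' Exclusions are evaluated in a fixed order, each patient counted once at the
#' first applicable criterion: (1) discontinuers - the last in-window
#' originator dispensation's supply plus the grace period ends before the
#' index date; (2) switchers - a biosimilar or other-biologic dispensation
#' after the last originator dispensation and on/before index; (3) lack of
#' enrollment at index; (4) no public-plan (payer-accepted) in-window
#' originator dispensation.
#'
#' @param candidates A `cohort_candidates` from
#'   [identify_ibd_originator_users()].
#' @param bundle A `claims_bundle`.
#' @param definition A [cohort_definition()].
#' @param params A [cohort_params()].
#' @param role `"policy"` or `"historical"`.
#' @return A `cohort`: `definition`, `members`, `flow` ([patient_flow()]),
#'   `role`.
#' @export
apply_exclusions <- function(candidates, bundle, definition,
                             params = cohort_params(), role = "policy") {
  stopifnot(inherits(candidates, "cohort_candidates"))
  ids <- candidates$patients
  idx <- definition$index_date
  if (length(ids) == 0) {
    return(structure(
      list(definition = definition, members = character(0),
           flow = patient_flow(candidates$n_originator_users, 0L, 0L, 0L,
                               0L, 0L),
           role = role),
      class = "cohort"
    ))
  }
  dp <- bundle$dispensations[bundle$dispensations$patient_id %in% ids, ]

  orig_win <- dp[dp$drug_class == "originator_infliximab" &
                   dp$service_date >= definition$window_start &
                   dp$service_date <= definition$window_end, ]
  last_win <- orig_win |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      last_date = max(.data$service_date),
      last_supply = max(.data$days_supply[.data$service_date ==
                                            max(.data$service_date)]),
      .groups = "drop"
    )
  last_win <- last_win[match(ids, last_win$patient_id), ]
  # supply interval [date, date + supply) plus grace covers index?
  disc <- (last_win$last_date + last_win$last_supply + params$grace_days - 1L) < idx

  orig_all <- dp[dp$drug_class == "originator_infliximab" &
                   dp$service_date <= idx, ]
  last_orig <- orig_all |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(last_orig = max(.data$service_date), .groups = "drop")
  last_orig <- last_orig$last_orig[match(ids, last_orig$patient_id)]
  sw_disp <- dp[dp$drug_class %in% c("biosimilar_infliximab", "other_biologic") &
                  dp$service_date <= idx, ]
  last_sw <- if (nrow(sw_disp) == 0) {
    tibble::tibble(patient_id = character(0),
                   last_sw = as.Date(character(0)))
  } else {
    dplyr::group_by(sw_disp, .data$patient_id) |>
      dplyr::summarise(last_sw = max(.data$service_date), .groups = "drop")
  }
  sw_join <- dplyr::left_join(
    tibble::tibble(patient_id = ids, last_orig = last_orig),
    last_sw, by = "patient_id"
  )
  switcher <- !is.na(sw_join$last_sw) & sw_join$last_sw > sw_join$last_orig

  en <- bundle$enrollment[bundle$enrollment$patient_id %in% ids, ]
  enrolled <- unique(en$patient_id[en$start_date <= idx & en$end_date >= idx])
  no_enroll <- !(ids %in% enrolled)

  covered <- unique(orig_win$patient_id[orig_win$payer_accepted])
  no_pharma <- !(ids %in% covered)

  reason <- rep(NA_character_, length(ids))
  reason[no_pharma] <- "no_pharmacare"
  reason[no_enroll] <- "no_enrollment"
  reason[switcher] <- "switcher"
  reason[disc] <- "discontinuer"  # assigned last so it wins (first criterion)

  flow <- patient_flow(
    n_originator_users = candidates$n_originator_users,
    n_with_ibd = candidates$n_with_ibd,
    excluded_discontinuers = sum(reason == "discontinuer", na.rm = TRUE),
    excluded_switchers = sum(reason == "switcher", na.rm = TRUE),
    excluded_no_enrollment = sum(reason == "no_enrollment", na.rm = TRUE),
    excluded_no_pharmacare = sum(reason == "no_pharmacare", na.rm = TRUE)
  )
  members <- ids[is.na(reason)]
  structure(
    list(definition = definition, members = members, flow = flow, role = role),
    class = "cohort"
  )
}

#' Build one cohort for a year
#'
#' @inheritParams apply_exclusions
#' @param year Cohort year.
#' @export
build_cohort <- function(bundle, year, role = "historical",
                         params = cohort_params()) {
  definition <- cohort_definition(year)
  cand <- identify_ibd_originator_users(bundle, definition, params)
  apply_exclusions(cand, bundle, definition, params, role = role)
}

#' Build the policy cohort and all historical cohorts
#'
#' The highest year takes the policy role; all earlier years are historical
#' comparators. Patients may belong to several cohorts.
#'
#' @param bundle A `claims_bundle`.
#' @param years Integer vector of at least two cohort years.
#' @param params A [cohort_params()].
#' @return A named list of `cohort` objects (class `cohort_set`), ordered by
#'   year.
#' @export
build_all_cohorts <- function(bundle, years, params = cohort_params()) {
  years <- sort(unique(as.integer(years)))
  if (length(years) < 2) {
    stop_ss("at least two cohort years are required (one policy, >=1 historical)",
            "configuration_error")
  }
  policy_year <- max(years)
  cohorts <- lapply(years, function(y) {
    build_cohort(bundle, y,
                 role = if (y == policy_year) "policy" else "historical",
                 params = params)
  })
  names(cohorts) <- as.character(years)
  structure(cohorts, class = "cohort_set")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort %d (%s)> %d members (of %d IBD originator users)\n",
              x$definition$year, x$role, length(x$members), x$flow$n_with_ibd))
  invisible(x)
}
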