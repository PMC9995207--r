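# Paper-shaped outputs: monthly biosimilar market share, patient-flow and
# characteristics tables, and per-endpoint cumulative-incidence panels with
# shaded signal regions. Table renderers are pure functions of their inputs.

#' Monthly biosimilar share of infliximab dispensations
#'
#' For each calendar month (by service date) and stratum, the percentage of
#' all infliximab dispensations (originator plus biosimilar) that were for a
#' biosimilar. Strata cross age at dispensation (adult = 18 or older) with
#' payer acceptance (`all` dispensations vs `payer_accepted` only). Months
#' with no infliximab dispensations in a stratum are flagged missing rather
#' than reported as 0.
#'
#' @param bundle A `claims_bundle`.
#' @param months Optional `Date` vector of first-of-month values delimiting
#'   the reporting window (`c(from, to)`, inclusive). Defaults to the full
#'   range of infliximab dispensations on record.
#' @return A tibble with columns `month`, `age_group`, `coverage`,
#'   `n_dispensations`, `n_biosimilar`, `share` (percent, `NA` when missing)
#'   and `missing`.
#' @export
monthly_biosimilar_share <- function(bundle, months = NULL) {
  dp <- bundle$dispensations
  dp <- dp[dp$drug_class %in% c("originator_infliximab",
                                "biosimilar_infliximab"), ]
  en <- dplyr::distinct(bundle$enrollment, .data$patient_id, .keep_all = TRUE)
  dp$birth_year <- en$birth_year[match(dp$patient_id, en$patient_id)]
  dp$month <- as.Date(format(dp$service_date, "%Y-%m-01"))
  dp$age_group <- ifelse(
    !is.na(dp$birth_year) &
      (as.integer(format(dp$service_date, "%Y")) - dp$birth_year) >= 18,
    "adult", "pediatric"
  )
  if (is.null(months)) {
    if (nrow(dp) == 0) {
      return(tibble::tibble(month = as.Date(character(0)),
                            age_group = character(0), coverage = character(0),
                            n_dispensations = integer(0),
                            n_biosimilar = integer(0), share = double(0),
                            missing = logical(0)))
    }
    months <- range(dp$month)
  }
  month_seq <- seq(months[1], months[2], by = "month")

  one_stratum <- function(d, age_group, coverage) {
    agg <- d |>
      dplyr::group_by(.data$month) |>
      dplyr::summarise(
        n_dispensations = dplyr::n(),
        n_biosimilar = sum(.data$drug_class == "biosimilar_infliximab"),
        .groups = "drop"
      )
    out <- dplyr::left_join(tibble::tibble(month = month_seq), agg,
                            by = "month")
    out$n_dispensations[is.na(out$n_dispensations)] <- 0L
    out$n_biosimilar[is.na(out$n_biosimilar)] <- 0L
    out$age_group <- age_group
    out$coverage <- coverage
    out$missing <- out$n_dispensations == 0L
    out$share <- ifelse(out$missing, NA_real_,
                        100 * out$n_biosimilar / out$n_dispensations)
    out[, c("month", "age_group", "coverage", "n_dispensations",
            "n_biosimilar", "share", "missing")]
  }
  dplyr::bind_rows(
    one_stratum(dp[dp$age_group == "adult", ], "adult", "all"),
    one_stratum(dp[dp$age_group == "adult" & dp$payer_accepted, ], "adult",
                "payer_accepted"),
    one_stratum(dp[dp$age_group == "pediatric", ], "pediatric", "all"),
    one_stratum(dp[dp$age_group == "pediatric" & dp$payer_accepted, ],
                "pediatric", "payer_accepted")
  )
}

#' Patient-flow table across cohorts
#'
#' One column per cohort with inclusion counts, exclusion counts with
#' percentages of originator users (one decimal, ties rounded away from
#' zero), and the final cohort size.
#'
#' @param cohorts A `cohort_set` (or list of `cohort` objects).
#' @return A tibble with one row per flow quantity (`row`) and one column per
#'   cohort year, cells formatted as `n` or `n (pct)`.
#' @export
patient_flow_table <- function(cohorts) {
  cols <- lapply(cohorts, function(coh) {
    fl <- coh$flow
    pct <- function(k) {
      if (fl$n_originator_users == 0) return(sprintf("%d (0.0)", k))
      sprintf("%d (%.1f)", k,
              round_half_up(100 * k / fl$n_originator_users, 1))
    }
    c(
      originator_users = sprintf("%d", fl$n_originator_users),
      with_ibd = sprintf("%d", fl$n_with_ibd),
      excluded_discontinuers = pct(fl$excluded_discontinuers),
      excluded_switchers = pct(fl$excluded_switchers),
      excluded_no_enrollment = pct(fl$excluded_no_enrollment),
      excluded_no_pharmacare = pct(fl$excluded_no_pharmacare),
      final_cohort = sprintf("%d", fl$n_final)
    )
  })
  out <- tibble::tibble(row = names(cols[[1]]))
  for (nm in names(cohorts)) {
    label <- sprintf("%s (%s)", nm, cohorts[[nm]]$role)
    out[[label]] <- unname(cols[[nm]])
  }
  out
}

#' Characteristics table across cohorts
#'
#' Per-cohort summary statistics computed from the claims bundle: age at
#' index (mean, SD, median, range), sex, IBD-flagged record in the prior
#' year, years since first infliximab dispensation on record, and prior-year
#' outpatient visit and hospital-night counts. SD is reported missing for
#' single-patient cohorts.
#'
#' @param cohorts A `cohort_set`.
#' @param bundle The `claims_bundle` the cohorts were built from.
#' @return A tibble with one row per statistic and one column per cohort.
#' @export
characteristics_table <- function(cohorts, bundle) {
  en <- dplyr::distinct(bundle$enrollment, .data$patient_id, .keep_all = TRUE)
  fmt1 <- function(x) sprintf("%.1f", round_half_up(x, 1))
  cols <- lapply(cohorts, function(coh) {
    def <- coh$definition
    ids <- coh$members
    n <- length(ids)
    if (n == 0) {
      return(stats::setNames(rep("-", nrow(character_rows())),
                             character_rows()$row))
    }
    idx <- def$index_date
    lb <- idx - 365L
    birth <- en$birth_year[match(ids, en$patient_id)]
    age <- def$year - birth
    sexes <- en$sex[match(ids, en$patient_id)]
    n_male <- sum(sexes == "male", na.rm = TRUE)
    n_female <- sum(sexes == "female", na.rm = TRUE)

    vs <- bundle$visits[bundle$visits$patient_id %in% ids, ]
    hs <- bundle$hospital[bundle$hospital$patient_id %in% ids, ]
    dp <- bundle$dispensations[bundle$dispensations$patient_id %in% ids, ]

    ibd_flagged <- unique(c(
      vs$patient_id[vs$diagnosis_flag_ibd & vs$service_date >= lb &
                      vs$service_date < idx],
      hs$patient_id[hs$diagnosis_flag_ibd & hs$admission_date >= lb &
                      hs$admission_date < idx]
    ))

    first_inflx <- dp[dp$drug_class %in% c("originator_infliximab",
                                           "biosimilar_infliximab"), ] |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first = min(.data$service_date), .groups = "drop")
    yrs <- as.numeric(idx - first_inflx$first[match(ids,
                                                    first_inflx$patient_id)]) /
      365.25

    pv <- vs[vs$setting == "outpatient" & vs$service_date >= lb &
               vs$service_date < idx, ] |>
      dplyr::count(.data$patient_id)
    visits_per <- pv$n[match(ids, pv$patient_id)]
    visits_per[is.na(visits_per)] <- 0L

    stays <- hs[hs$admission_date < idx & hs$discharge_date >= lb, ]
    if (nrow(stays) > 0) {
      nights <- as.numeric(pmin(stays$discharge_date, idx - 1L) -
                             pmax(stays$admission_date, lb)) + 1
      nh <- tibble::tibble(patient_id = stays$patient_id, nights = nights) |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::summarise(nights = sum(.data$nights), .groups = "drop")
      nights_per <- nh$nights[match(ids, nh$patient_id)]
      nights_per[is.na(nights_per)] <- 0
    } else {
      nights_per <- rep(0, n)
    }

    sd_or_na <- function(x) if (length(x) > 1) fmt1(sd(x)) else "NA"
    c(
      n = sprintf("%d", n),
      age_mean_sd = sprintf("%s (%s)", fmt1(mean(age)), sd_or_na(age)),
      age_median_range = sprintf("%.1f (%.1f-%.1f)", median(age), min(age),
                                 max(age)),
      female_n_pct = sprintf("%d (%s)", n_female,
                             fmt1(100 * n_female / n)),
      male_n_pct = sprintf("%d (%s)", n_male, fmt1(100 * n_male / n)),
      ibd_flag_prior_year = sprintf("%d (%s)", sum(ids %in% ibd_flagged),
                                    fmt1(100 * sum(ids %in% ibd_flagged) / n)),
      years_since_first_infliximab = sprintf("%s (%s)",
                                             fmt1(mean(yrs, na.rm = TRUE)),
                                             sd_or_na(yrs[!is.na(yrs)])),
      visits_prior_year = sprintf("%s (%s)", fmt1(mean(visits_per)),
                                  sd_or_na(visits_per)),
      hospital_nights_prior_year = sprintf("%s (%s)", fmt1(mean(nights_per)),
                                           sd_or_na(nights_per))
    )
  })
  out <- tibble::tibble(row = names(cols[[1]]))
  for (nm in names(cohorts)) {
    label <- sprintf("%s (%s)", nm, cohorts[[nm]]$role)
    out[[label]] <- unname(cols[[nm]])
  }
  out
}

character_rows <- function() {
  tibble::tibble(row = c(
    "n", "age_mean_sd", "age_median_range", "female_n_pct", "male_n_pct",
    "ibd_flag_prior_year", "years_since_first_infliximab",
    "visits_prior_year", "hospital_nights_prior_year"
  ))
}

#' Render cumulative-incidence panels with shaded signal regions
#'
#' One panel per endpoint: the policy cohort's and the historical-average
#' daily cumulative incidence, days where the likelihood ratio exceeds the
#' threshold shaded, and a vertical marker at the end of the transition
#' period.
#'
#' @param comparisons Named list of `endpoint_comparison` objects (from
#'   [monitor_endpoints()]).
#' @param directory Output directory for figure files.
#' @param formats File formats to emit (default `c("pdf", "png")`).
#' @param transition_day Day marking the end of the policy transition period
#'   (default 182); use `NULL` to omit the marker.
#' @return Invisibly, the character vector of files written.
#' @export
render_panels <- function(comparisons, directory,
                          formats = c("pdf", "png"), transition_day = 182L) {
  if (length(comparisons) == 0) {
    stop_ss("no comparison series supplied", "invalid_argument")
  }
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  }
  labels <- stats::setNames(endpoint_catalog()$label, endpoint_catalog()$name)
  files <- character(0)
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    s <- cmp$series
    if (nrow(s) == 0) stop_ss("empty comparison series", "invalid_argument")
    shade <- cmp$report$intervals
    long <- tibble::tibble(
      day = rep(s$day, 2),
      ci = c(s$ci_policy, s$ci_hist_mean),
      cohort = rep(c("policy", "historical mean"), each = nrow(s))
    )
    p <- ggplot2::ggplot(long)
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$start_day - 0.5,
                     xmax = .data$end_day + 0.5),
        ymin = -Inf, ymax = Inf, fill = "grey80", inherit.aes = FALSE
      )
    }
    p <- p +
      ggplot2::geom_step(ggplot2::aes(x = .data$day, y = .data$ci,
                                      colour = .data$cohort)) +
      ggplot2::scale_colour_manual(values = c("policy" = "#b2182b",
                                              "historical mean" = "#2166ac")) +
      ggplot2::labs(
        title = labels[nm] %||% nm,
        subtitle = sprintf("signal: %s; max difference %+.1f pp (day %d)",
                           cmp$report$classification, cmp$report$max_cid,
                           cmp$report$max_cid_day),
        x = "Follow-up day", y = "Cumulative incidence (%)", colour = NULL
      ) +
      ggplot2::theme_minimal()
    if (!is.null(transition_day)) {
      p <- p + ggplot2::geom_vline(xintercept = transition_day,
                                   linetype = "dashed", colour = "grey40")
    }
    for (fmt in formats) {
      f <- file.path(directory, sprintf("%s.%s", nm, fmt))
      ggplot2::ggsave(f, p, width = 7, height = 4.5, dpi = 150)
      files <- c(files, f)
    }
  }
  invisible(files)
}
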