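# End-to-end driver: simulate (or load) claims, build cohorts, ascertain
# endpoints, monitor signals, and write the full set of tables and reports.
# Outputs are deterministic: the same configuration and seed produce
# byte-identical files.

#' Serialize signal reports to JSON
#'
#' @param comparisons Named list of `endpoint_comparison` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_signal_report <- function(comparisons, path) {
  reports <- lapply(comparisons, function(cmp) {
    r <- cmp$report
    list(
      endpoint = r$endpoint,
      threshold = r$threshold,
      sustain_days = r$sustain_days,
      n_policy = r$n_policy,
      n_historical_pooled = r$n_historical_pooled,
      signal = r$signal,
      classification = r$classification,
      onset_day = r$onset_day,
      max_cid = r$max_cid,
      max_cid_day = r$max_cid_day,
      intervals = as.data.frame(r$intervals)
    )
  })
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full monitoring pipeline
#'
#' Simulates a claims bundle from `config` (or uses a supplied bundle),
#' builds the policy and historical cohorts, ascertains all endpoints,
#' monitors signals, and writes: the claims tables, the patient-flow and
#' characteristics tables, the monthly biosimilar share, the policy-cohort
#' switch curve, one comparison-series CSV per endpoint and a JSON signal
#' report.
#'
#' @param config A [scenario_config()]; ignored when `bundle` is given.
#' @param out_dir Output directory.
#' @param bundle Optional pre-built `claims_bundle`.
#' @param years Cohort years (default: the config's, or inferred is not
#'   attempted for external bundles).
#' @param threshold,sustain_days Signal rule parameters.
#' @param params [cohort_params()].
#' @param write_claims_tables Also write the four claims CSVs (default TRUE).
#' @param write_figures Render endpoint panels (default FALSE; figures are
#'   not byte-reproducible across graphics library builds, tables and
#'   reports are).
#' @return Invisibly, a list with `bundle`, `cohorts`, `comparisons`,
#'   `switch_curve`, and the output `paths`.
#' @export
run_pipeline <- function(config = scenario_config(), out_dir,
                         bundle = NULL, years = NULL,
                         threshold = default_signal_threshold(),
                         sustain_days = 30L, params = cohort_params(),
                         write_claims_tables = TRUE, write_figures = FALSE) {
  if (is.null(bundle)) {
    bundle <- simulate_claims(config)
    years <- years %||% config$cohort_years
  }
  if (is.null(years)) {
    stop_ss("cohort years must be supplied for an external bundle",
            "configuration_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE,
                                       showWarnings = FALSE)
  paths <- character(0)

  if (write_claims_tables) {
    paths <- c(paths, write_claims(bundle, file.path(out_dir, "claims")))
  }

  cohorts <- build_all_cohorts(bundle, years, params = params)
  roles <- vapply(cohorts, `[[`, character(1), "role")
  policy <- cohorts[[which(roles == "policy")]]

  flow_path <- file.path(out_dir, "patient_flow.csv")
  readr::write_csv(patient_flow_table(cohorts), flow_path, progress = FALSE)
  chars_path <- file.path(out_dir, "characteristics.csv")
  readr::write_csv(characteristics_table(cohorts, bundle), chars_path,
                   progress = FALSE)
  share_path <- file.path(out_dir, "monthly_biosimilar_share.csv")
  readr::write_csv(monthly_biosimilar_share(bundle), share_path,
                   progress = FALSE)
  curve <- biosimilar_switch_curve(bundle, policy)
  curve_path <- file.path(out_dir, "switch_curve.csv")
  readr::write_csv(curve, curve_path, progress = FALSE)

  comparisons <- monitor_endpoints(bundle, cohorts, threshold = threshold,
                                   sustain_days = sustain_days)
  series_dir <- file.path(out_dir, "comparison_series")
  if (!dir.exists(series_dir)) dir.create(series_dir, showWarnings = FALSE)
  series_paths <- vapply(names(comparisons), function(nm) {
    f <- file.path(series_dir, paste0(nm, ".csv"))
    readr::write_csv(comparisons[[nm]]$series, f, progress = FALSE)
    f
  }, character(1))
  signal_path <- file.path(out_dir, "signal_report.json")
  write_signal_report(comparisons, signal_path)

  fig_paths <- character(0)
  if (write_figures) {
    fig_paths <- render_panels(comparisons, file.path(out_dir, "figures"))
  }

  invisible(list(
    bundle = bundle, cohorts = cohorts, comparisons = comparisons,
    switch_curve = curve,
    paths = c(paths, flow = flow_path, characteristics = chars_path,
              share = share_path, switch_curve = curve_path, series_paths,
              signal_report = signal_path, fig_paths)
  ))
}
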