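# Claims data model: four delimited-text tables shared by every stage of the
# pipeline. Dates are ISO-8601 (YYYY-MM-DD); drugs are carried as a closed
# drug_class vocabulary rather than DIN/ATC codes.

#' Controlled vocabularies of the claims data model
#'
#' @return A named list of character vectors: `drug_class`, `sex`,
#'   `prescriber_specialty`, `provider_type`, `specialty`, `setting`,
#'   `admission_category`.
#' @export
claims_vocabulary <- function() {
  list(
    drug_class = c(
      "originator_infliximab", "biosimilar_infliximab", "other_biologic",
      "antibiotic_ibd", "prednisone", "other_systemic_corticosteroid", "other"
    ),
    sex = c("female", "male"),
    prescriber_specialty = c("gastroenterology", "other"),
    provider_type = c("physician", "nurse_practitioner"),
    specialty = c("gastroenterology", "other"),
    setting = c("outpatient", "emergency_department"),
    admission_category = c("emergency", "elective")
  )
}

#' Column schemas of the four claims tables
#'
#' @return Named list (enrollment, dispensations, visits, hospital) of
#'   `readr` column specifications.
#' @export
claims_schemas <- function() {
  list(
    enrollment = readr::cols(
      patient_id = readr::col_character(),
      start_date = readr::col_date(format = "%Y-%m-%d"),
      end_date = readr::col_date(format = "%Y-%m-%d"),
      birth_year = readr::col_integer(),
      sex = readr::col_character()
    ),
    dispensations = readr::cols(
      patient_id = readr::col_character(),
      service_date = readr::col_date(format = "%Y-%m-%d"),
      drug_class = readr::col_character(),
      brand = readr::col_character(),
      quantity_mg = readr::col_double(),
      days_supply = readr::col_integer(),
      prescriber_specialty = readr::col_character(),
      payer_accepted = readr::col_logical()
    ),
    visits = readr::cols(
      patient_id = readr::col_character(),
      service_date = readr::col_date(format = "%Y-%m-%d"),
      provider_type = readr::col_character(),
      specialty = readr::col_character(),
      setting = readr::col_character(),
      diagnosis_flag_ibd = readr::col_logical()
    ),
    hospital = readr::cols(
      patient_id = readr::col_character(),
      admission_date = readr::col_date(format = "%Y-%m-%d"),
      discharge_date = readr::col_date(format = "%Y-%m-%d"),
      admission_category = readr::col_character(),
      diagnosis_flag_ibd = readr::col_logical()
    )
  )
}

empty_table <- function(name) {
  spec <- claims_schemas()[[name]]
  cols <- lapply(spec$cols, function(ct) {
    switch(class(ct)[1],
      collector_character = character(0),
      collector_date = as.Date(character(0)),
      collector_integer = integer(0),
      collector_double = double(0),
      collector_logical = logical(0)
    )
  })
  tibble::as_tibble(cols)
}

#' Construct a claims bundle
#'
#' Bundles the four claims tables (enrollment spans, pharmacy dispensations,
#' outpatient/ED visits, hospital stays) into a single validated object.
#'
#' @param enrollment,dispensations,visits,hospital Data frames following the
#'   schemas of [claims_schemas()]. Missing tables default to empty.
#' @param validate If `TRUE` (default), invariant violations raise an error
#'   listing every offending row.
#' @return An object of class `claims_bundle`: a named list of four tibbles.
#' @export
claims_bundle <- function(enrollment = NULL, dispensations = NULL,
                          visits = NULL, hospital = NULL, validate = TRUE) {
  b <- structure(
    list(
      enrollment = coerce_table(enrollment, "enrollment"),
      dispensations = coerce_table(dispensations, "dispensations"),
      visits = coerce_table(visits, "visits"),
      hospital = coerce_table(hospital, "hospital")
    ),
    class = "claims_bundle"
  )
  if (validate) {
    issues <- validate_claims(b)
    if (nrow(issues) > 0) {
      stop_ss(
        paste0(
          "claims bundle failed validation (", nrow(issues), " problem(s)):\n",
          paste(utils::capture.output(print(as.data.frame(utils::head(issues, 20)))),
                collapse = "\n")
        ),
        "claims_validation_error"
      )
    }
  }
  b
}

coerce_table <- function(x, name) {
  tmpl <- empty_table(name)
  if (is.null(x)) return(tmpl)
  x <- tibble::as_tibble(x)
  missing <- setdiff(names(tmpl), names(x))
  if (length(missing) > 0) {
    stop_ss(
      sprintf("table '%s' is missing column(s): %s", name,
              paste(missing, collapse = ", ")),
      "claims_schema_error"
    )
  }
  x <- x[names(tmpl)]
  for (col in names(tmpl)) {
    if (inherits(tmpl[[col]], "Date")) x[[col]] <- as.Date(x[[col]])
    else if (is.integer(tmpl[[col]])) x[[col]] <- as.integer(x[[col]])
    else if (is.double(tmpl[[col]])) x[[col]] <- as.double(x[[col]])
    else if (is.logical(tmpl[[col]])) x[[col]] <- as.logical(x[[col]])
    else x[[col]] <- as.character(x[[col]])
  }
  x
}

#' Validate a claims bundle
#'
#' Checks every record against the data-model invariants. Validation is total:
#' no record is dropped, and every rejection carries the table, row number and
#' reason.
#'
#' @param bundle A `claims_bundle`.
#' @return A tibble with columns `table`, `row`, `patient_id`, `problem`
#'   (zero rows when the bundle is valid).
#' @export
validate_claims <- function(bundle) {
  voc <- claims_vocabulary()
  out <- list()
  add <- function(table, rows, ids, problem) {
    if (length(rows) > 0) {
      out[[length(out) + 1]] <<- tibble::tibble(
        table = table, row = as.integer(rows),
        patient_id = as.character(ids), problem = problem
      )
    }
  }
  flag <- function(table, bad, ids, problem) {
    bad <- which(bad %in% TRUE | is.na(bad))
    add(table, bad, ids[bad], problem)
  }

  en <- bundle$enrollment
  flag("enrollment", en$start_date > en$end_date, en$patient_id,
       "start_date after end_date")
  flag("enrollment", !(en$sex %in% voc$sex), en$patient_id, "invalid sex")
  if (nrow(en) > 1) {
    en2 <- dplyr::arrange(dplyr::mutate(en, ..row = dplyr::row_number()),
                          .data$patient_id, .data$start_date)
    ov <- en2 |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(..overlap = .data$start_date <= dplyr::lag(.data$end_date)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$..overlap %in% TRUE)
    add("enrollment", ov$..row, ov$patient_id, "overlapping enrollment spans")
  }

  dp <- bundle$dispensations
  flag("dispensations", !(dp$quantity_mg > 0), dp$patient_id,
       "quantity_mg must be > 0")
  flag("dispensations", !(dp$days_supply >= 1L), dp$patient_id,
       "days_supply must be >= 1")
  flag("dispensations", !(dp$drug_class %in% voc$drug_class), dp$patient_id,
       "invalid drug_class")
  flag("dispensations", !(dp$prescriber_specialty %in% voc$prescriber_specialty),
       dp$patient_id, "invalid prescriber_specialty")
  flag("dispensations", is.na(dp$service_date), dp$patient_id,
       "missing/unparseable service_date")

  vs <- bundle$visits
  flag("visits", !(vs$provider_type %in% voc$provider_type), vs$patient_id,
       "invalid provider_type")
  flag("visits", !(vs$specialty %in% voc$specialty), vs$patient_id,
       "invalid specialty")
  flag("visits", !(vs$setting %in% voc$setting), vs$patient_id,
       "invalid setting")
  flag("visits", is.na(vs$service_date), vs$patient_id,
       "missing/unparseable service_date")

  hs <- bundle$hospital
  flag("hospital", hs$admission_date > hs$discharge_date, hs$patient_id,
       "admission_date after discharge_date")
  flag("hospital", !(hs$admission_category %in% voc$admission_category),
       hs$patient_id, "invalid admission_category")

  if (length(out) == 0) {
    tibble::tibble(table = character(0), row = integer(0),
                   patient_id = character(0), problem = character(0))
  } else {
    dplyr::bind_rows(out)
  }
}

table_file_names <- c(
  enrollment = "enrollment.csv", dispensations = "dispensations.csv",
  visits = "visits.csv", hospital = "hospital.csv"
)

#' Read a claims bundle from delimited-text files
#'
#' @param paths Either a directory containing `enrollment.csv`,
#'   `dispensations.csv`, `visits.csv` and `hospital.csv`, or a named
#'   character vector/list mapping those table names to file paths.
#' @param validate Passed to [claims_bundle()].
#' @return A `claims_bundle`.
#' @details A missing column raises a schema error naming the column; an
#'   unparseable date raises a row-level error with the offending line number.
#' @export
read_claims <- function(paths, validate = TRUE) {
  if (length(paths) == 1 && is.character(paths) && is.null(names(paths))) {
    paths <- file.path(paths, table_file_names)
    names(paths) <- names(table_file_names)
  }
  paths <- unlist(paths)
  schemas <- claims_schemas()
  tables <- list()
  for (nm in names(table_file_names)) {
    path <- paths[[nm]]
    if (is.null(path) || !file.exists(path)) {
      stop_ss(sprintf("file for table '%s' not found: %s", nm,
                      path %||% "<missing>"), "claims_io_error")
    }
    header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                    show_col_types = FALSE))
    expected <- names(schemas[[nm]]$cols)
    missing <- setdiff(expected, header)
    if (length(missing) > 0) {
      stop_ss(sprintf("table '%s' (%s) is missing column(s): %s", nm, path,
                      paste(missing, collapse = ", ")), "claims_schema_error")
    }
    # readr's parse warning is superseded by the row-level error below
    tb <- suppressWarnings(
      readr::read_csv(path, col_types = schemas[[nm]],
                      locale = readr::locale(encoding = "UTF-8"),
                      progress = FALSE, show_col_types = FALSE, lazy = FALSE)
    )
    probs <- readr::problems(tb)
    if (nrow(probs) > 0) {
      stop_ss(
        paste0(sprintf("table '%s' (%s) has unparseable value(s):\n", nm, path),
               paste(sprintf("  line %d, column %d: expected %s, got '%s'",
                             probs$row, probs$col, probs$expected,
                             probs$actual), collapse = "\n")),
        "claims_parse_error"
      )
    }
    tables[[nm]] <- tb
  }
  claims_bundle(tables$enrollment, tables$dispensations, tables$visits,
                tables$hospital, validate = validate)
}

#' Write a claims bundle to delimited-text files
#'
#' Serializes the four tables as UTF-8 CSV with ISO-8601 dates, such that
#' `read_claims(write_claims(b, dir))` reproduces `b` field for field.
#'
#' @param bundle A `claims_bundle`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_claims <- function(bundle, directory) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_ss(sprintf("cannot create directory '%s'", directory),
                     "claims_io_error")
  }
  paths <- file.path(directory, table_file_names)
  names(paths) <- names(table_file_names)
  for (nm in names(paths)) {
    readr::write_csv(bundle[[nm]], paths[[nm]], progress = FALSE)
  }
  invisible(paths)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in names(table_file_names)) {
    cat(sprintf("  %-14s %6d records, %d patients\n", nm, nrow(x[[nm]]),
                dplyr::n_distinct(x[[nm]]$patient_id)))
  }
  invisible(x)
}

# number of distinct patients anywhere in the bundle
bundle_patients <- function(bundle) {
  unique(c(bundle$enrollment$patient_id, bundle$dispensations$patient_id,
           bundle$visits$patient_id, bundle$hospital$patient_id))
}
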