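#' Read and write cohort CSV files
#'
#' One row per patient, header exactly as the patient-record field names,
#' categorical fields as lowercase tokens (`smoking_status` in
#' nonsmoker/former/current, `ses_class` in i/ii/iii/iv/v, `high_stress` in
#' true/false). `cigarettes_per_day` may be empty only for non-current
#' smokers. Reading validates every record and reports the offending CSV
#' line on failure; writing then reading returns the identical cohort.
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the validated cohort tibble.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' cohort <- generate_cohort(cohort_config(n_patients = 5))
#' write_cohort_csv(cohort, path)
#' identical(read_cohort_csv(path), cohort)
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort |>
    dplyr::mutate(
      ses_class = tolower(.data$ses_class),
      high_stress = tolower(as.character(.data$high_stress))
    )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cohort file not found: ", path))
  if (file.size(path) == 0) rlang::abort(paste0("empty cohort file: ", path))
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      patient_id = readr::col_character(),
      age = readr::col_integer(),
      bop_extent = readr::col_double(),
      pockets_over_5mm = readr::col_integer(),
      teeth_lost = readr::col_integer(),
      smoking_status = readr::col_character(),
      cigarettes_per_day = readr::col_integer(),
      al_age_ratio = readr::col_double(),
      glycemic_value = readr::col_double(),
      dental_systemic_status = readr::col_integer(),
      ses_class = readr::col_character(),
      high_stress = readr::col_logical()
    ), na = "", progress = FALSE, show_col_types = FALSE),
    error = function(e) rlang::abort(paste0("cannot parse cohort CSV: ",
                                            conditionMessage(e)))
  )
  if (nrow(raw) == 0) {
    rlang::abort(paste0("empty cohort file: ", path))
  }
  problems <- readr::problems(raw)
  if (nrow(problems) > 0) {
    rlang::abort(sprintf("malformed cohort CSV at line %d: expected %s, got %s",
                         problems$row[1] + 1L, problems$expected[1],
                         problems$actual[1]))
  }
  attr(raw, "spec") <- NULL
  attr(raw, "problems") <- NULL
  cohort <- raw |>
    dplyr::mutate(ses_class = toupper(.data$ses_class))
  for (i in seq_len(nrow(cohort))) {
    tryCatch(
      validate_cohort(cohort[i, ]),
      periorisk_validation_error = function(e) {
        rlang::abort(sprintf("line %d: %s", i + 1L, conditionMessage(e)),
                     class = "periorisk_validation_error")
      }
    )
  }
  validate_cohort(cohort)
  cohort
}
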