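#' Axis scoring for the periodontal risk assessment coding system
#'
#' Each clinical parameter is mapped to an integer axis score 0--5 by a banded
#' lookup. The printed bands leave small gaps between adjacent rows (e.g. BOP
#' "<4" followed by "5-9"); bands are closed by treating each band's upper edge
#' as inclusive and extending it to the next band's floor, so every valid input
#' maps to exactly one score. All scoring functions are vectorised and
#' monotone non-decreasing in their numeric argument.
#'
#' @name axis-scoring
#' @rdname axis-scoring
NULL

stop_invalid <- function(field, value, why, patient_id = NULL) {
  who <- if (is.null(patient_id)) "" else paste0(" [patient ", patient_id, "]")
  rlang::abort(
    sprintf("invalid `%s`%s: %s (got %s)", field, who, why,
            paste(format(value), collapse = ", ")),
    class = "periorisk_validation_error",
    field = field, value = value, patient_id = patient_id
  )
}

check_num <- function(x, field, lo = 0, hi = Inf, lo_open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_invalid(field, x, "must be numeric and non-missing")
  }
  bad <- if (lo_open) x <= lo | x > hi else x < lo | x > hi
  if (any(bad)) {
    bound <- if (lo_open) sprintf("must be > %g and <= %g", lo, hi)
             else if (is.finite(hi)) sprintf("must be in [%g, %g]", lo, hi)
             else sprintf("must be >= %g", lo)
    stop_invalid(field, x[bad], bound)
  }
  invisible(x)
}

#' @describeIn axis-scoring Score bleeding-on-probing extent (percent of
#'   probed sites that bleed, 0--100). Bands: 0; (0,4]; (4,9]; (9,16];
#'   (16,25]; >25.
#' @param bop_extent Percent of probed sites bleeding, in \[0, 100\].
#' @return An integer vector of axis scores in 0--5.
#' @examples
#' score_bop(c(0, 7, 30))   # 0 2 5
#' score_diabetic(120)      # 3
#' score_al_age(1.2)        # 5
#' @export
score_bop <- function(bop_extent) {
  check_num(bop_extent, "bop_extent", 0, 100)
  findInterval(bop_extent, c(0, 4, 9, 16, 25), left.open = TRUE)
}

#' @describeIn axis-scoring Score the count of sites/areas with probing depth
#'   over 5 mm. Bands: 0; 1--2; 3--4; 5--6; 7--8; >=9.
#' @param pockets_over_5mm Non-negative integer count of deep-pocket sites.
#' @export
score_pockets <- function(pockets_over_5mm) {
  check_num(pockets_over_5mm, "pockets_over_5mm", 0)
  findInterval(pockets_over_5mm, c(0, 2, 4, 6, 8), left.open = TRUE)
}

#' @describeIn axis-scoring Score the count of missing teeth (same band
#'   structure as `score_pockets`).
#' @param teeth_lost Non-negative integer count of missing teeth.
#' @export
score_tooth_loss <- function(teeth_lost) {
  check_num(teeth_lost, "teeth_lost", 0)
  findInterval(teeth_lost, c(0, 2, 4, 6, 8), left.open = TRUE)
}

#' @describeIn axis-scoring Score smoking exposure. Non-smokers score 0,
#'   former smokers 1; current smokers score by cigarettes per day:
#'   <10 -> 2, 10--19 -> 3, 20 -> 4, >20 -> 5.
#' @param smoking_status One of `"nonsmoker"`, `"former"`, `"current"`.
#' @param cigarettes_per_day Non-negative count; required for current smokers.
#' @export
score_smoking <- function(smoking_status, cigarettes_per_day = NA_real_) {
  if (!all(smoking_status %in% c("nonsmoker", "former", "current"))) {
    stop_invalid("smoking_status",
                 setdiff(smoking_status, c("nonsmoker", "former", "current")),
                 "must be one of nonsmoker/former/current")
  }
  n <- max(length(smoking_status), length(cigarettes_per_day))
  smoking_status <- rep_len(smoking_status, n)
  cigarettes_per_day <- rep_len(cigarettes_per_day, n)
  cur <- smoking_status == "current"
  if (any(cur & (is.na(cigarettes_per_day) | cigarettes_per_day < 0))) {
    stop_invalid("cigarettes_per_day", cigarettes_per_day[cur],
                 "current smokers need a non-negative cigarettes/day count")
  }
  out <- integer(n)
  out[smoking_status == "former"] <- 1L
  out[cur] <- 2L + findInterval(cigarettes_per_day[cur], c(10, 20, 21))
  out
}

#' @describeIn axis-scoring Score the attachment-loss-to-age ratio.
#'   Bands: 0; (0,0.25]; (0.25,0.5]; (0.5,0.75]; (0.75,1]; >1.
#' @param al_age_ratio Non-negative real ratio (attachment loss / age).
#' @export
score_al_age <- function(al_age_ratio) {
  check_num(al_age_ratio, "al_age_ratio", 0)
  findInterval(al_age_ratio, c(0, 0.25, 0.5, 0.75, 1), left.open = TRUE)
}

#' @describeIn axis-scoring Score glycemic (diabetic) status in mg/dL.
#'   Bands: <102; 102--109; 110--117; 118--125; 126--133; >133.
#' @param glycemic_value Positive glycemic measurement in mg/dL.
#' @export
score_diabetic <- function(glycemic_value) {
  check_num(glycemic_value, "glycemic_value", 0, Inf, lo_open = TRUE)
  findInterval(glycemic_value, c(102, 110, 118, 126, 134))
}

#' @describeIn axis-scoring Score the dental-status / systemic-factors
#'   interplay. The ordinal status code (0 healthy ... 5 severe with tooth
#'   morbidity) is itself the axis score.
#' @param dental_systemic_status Integer status code in 0--5.
#' @export
score_dental_systemic <- function(dental_systemic_status) {
  check_num(dental_systemic_status, "dental_systemic_status", 0, 5)
  if (any(dental_systemic_status != round(dental_systemic_status))) {
    stop_invalid("dental_systemic_status", dental_systemic_status,
                 "must be an integer code 0-5")
  }
  as.integer(dental_systemic_status)
}

#' @describeIn axis-scoring Score socioeconomic/stress background
#'   characteristics: Kuppuswamy class I--V maps to 0--4, plus 1 for a
#'   high-stress indicator, capped at 5. This axis has no published coding
#'   table; the mapping is a fixed package convention isolated here so it can
#'   be swapped.
#' @param ses_class Kuppuswamy socioeconomic class, one of `"I"`..`"V"`.
#' @param high_stress Logical high-stress indicator.
#' @export
score_background <- function(ses_class, high_stress) {
  classes <- c("I", "II", "III", "IV", "V")
  if (!all(ses_class %in% classes)) {
    stop_invalid("ses_class", setdiff(ses_class, classes),
                 "must be a Kuppuswamy class I-V")
  }
  if (!is.logical(high_stress) || anyNA(high_stress)) {
    stop_invalid("high_stress", high_stress, "must be TRUE/FALSE")
  }
  pmin(match(ses_class, classes) - 1L + as.integer(high_stress), 5L)
}

#' Score a cohort of patient records on a model's axes
#'
#' Applies the per-axis coding functions to every row of a patient-record
#' data frame, in the axis order fixed by the model, and returns the scores
#' in long form together with the risk zone each score falls in.
#'
#' @param cohort A data frame of patient records with the columns
#'   `patient_id`, `age`, `bop_extent`, `pockets_over_5mm`, `teeth_lost`,
#'   `smoking_status`, `cigarettes_per_day`, `al_age_ratio`,
#'   `glycemic_value`, `dental_systemic_status`, `ses_class`, `high_stress`.
#' @param model A model spec from [pra_model()], or a model id
#'   (`"modified8"` or `"lt2003"`).
#' @return A tibble with one row per patient per axis: `patient_id`,
#'   `model_id`, `axis` (ordered factor in the model's axis order), `score`
#'   (integer 0--5) and `zone` (low/moderate/high).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5))
#' score_cohort(cohort, "modified8")
#' @export
score_cohort <- function(cohort, model = "modified8") {
  model <- as_pra_model(model)
  validate_cohort(cohort)
  all_scores <- tibble::tibble(
    bop             = score_bop(cohort$bop_extent),
    pockets         = score_pockets(cohort$pockets_over_5mm),
    tooth_loss      = score_tooth_loss(cohort$teeth_lost),
    smoking         = score_smoking(cohort$smoking_status,
                                    cohort$cigarettes_per_day),
    al_age          = score_al_age(cohort$al_age_ratio),
    diabetic        = score_diabetic(cohort$glycemic_value),
    dental_systemic = score_dental_systemic(cohort$dental_systemic_status),
    background      = score_background(cohort$ses_class, cohort$high_stress)
  )
  all_scores |>
    dplyr::select(dplyr::all_of(model$axis_names)) |>
    dplyr::mutate(patient_id = cohort$patient_id, .before = 1) |>
    tidyr::pivot_longer(-"patient_id", names_to = "axis",
                        values_to = "score") |>
    dplyr::mutate(
      model_id = model$model_id,
      axis = factor(.data$axis, levels = model$axis_names),
      zone = risk_zone(.data$score),
      .after = "patient_id"
    )
}

cohort_columns <- c(
  "patient_id", "age", "bop_extent", "pockets_over_5mm", "teeth_lost",
  "smoking_status", "cigarettes_per_day", "al_age_ratio", "glycemic_value",
  "dental_systemic_status", "ses_class", "high_stress"
)

#' Validate a cohort of patient records
#'
#' Checks the structural contract of a patient-record data frame: required
#' columns, age within the 30--60 study window, at most 12 missing teeth
#' (at least 20 functional teeth out of a 32-tooth baseline dentition),
#' ranges of all measurements, and that cigarettes/day is present for
#' current smokers. Errors name the patient, field and offending value.
#'
#' @inheritParams score_cohort
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) {
    rlang::abort("`cohort` must be a data frame of patient records")
  }
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    rlang::abort(paste0("cohort is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cohort) == 0) rlang::abort("cohort is empty")
  if (anyDuplicated(cohort$patient_id)) {
    stop_invalid("patient_id", cohort$patient_id[duplicated(cohort$patient_id)],
                 "must be unique")
  }
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    pid <- row$patient_id
    with_pid <- function(expr) {
      tryCatch(expr, periorisk_validation_error = function(e) {
        rlang::abort(sub("^invalid `([^`]+)`", sprintf("invalid `\\1` [patient %s]", pid),
                         conditionMessage(e)),
                     class = "periorisk_validation_error",
                     field = e$field, value = e$value, patient_id = pid)
      })
    }
    if (!is.numeric(row$age) || is.na(row$age) || row$age < 30 || row$age > 60) {
      stop_invalid("age", row$age, "must be in [30, 60]", pid)
    }
    if (row$teeth_lost > 12) {
      stop_invalid("teeth_lost", row$teeth_lost,
                   "must be <= 12 (at least 20 functional teeth)", pid)
    }
    with_pid(score_bop(row$bop_extent))
    with_pid(score_pockets(row$pockets_over_5mm))
    with_pid(score_tooth_loss(row$teeth_lost))
    with_pid(score_smoking(row$smoking_status, row$cigarettes_per_day))
    with_pid(score_al_age(row$al_age_ratio))
    with_pid(score_diabetic(row$glycemic_value))
    with_pid(score_dental_systemic(row$dental_systemic_status))
    with_pid(score_background(row$ses_class, row$high_stress))
  }
  invisible(cohort)
}
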