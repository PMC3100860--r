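#' Run the full risk-assessment study on a cohort
#'
#' Scores and classifies every patient under each requested model and
#' aggregates the comparison report: per-model category distributions, the
#' cross-model contingency table (when exactly two models are run), the
#' per-patient classification records and a provenance block (cohort size,
#' cohort hash, models). The report is a pure function of its inputs.
#'
#' @inheritParams score_cohort
#' @param models Character vector of model ids (default both models).
#' @return A `pra_study` object; see [tidy.pra_study()] and
#'   [glance.pra_study()] for tabular views.
#' @examples
#' study <- run_study(generate_cohort(cohort_config()))
#' study$counts
#' @export
run_study <- function(cohort, models = c("modified8", "lt2003")) {
  if (length(models) < 1) rlang::abort("at least one model is required")
  validate_cohort(cohort)
  models <- lapply(models, as_pra_model)
  classifications <- purrr::map(models, ~ classify_cohort(cohort, .x)) |>
    purrr::list_rbind()
  counts <- classifications |>
    dplyr::count(.data$model_id, .data$category, name = "n") |>
    tidyr::complete(model_id = purrr::map_chr(models, "model_id"),
                    category = factor(risk_levels, levels = risk_levels,
                                      ordered = TRUE),
                    fill = list(n = 0L)) |>
    dplyr::arrange(.data$model_id, .data$category)
  contingency <- NULL
  if (length(models) == 2) {
    wide <- classifications |>
      dplyr::select("patient_id", "model_id", "category") |>
      tidyr::pivot_wider(names_from = "model_id", values_from = "category")
    contingency <- table(wide[[models[[1]]$model_id]],
                         wide[[models[[2]]$model_id]],
                         dnn = c(models[[1]]$model_id, models[[2]]$model_id))
  }
  structure(
    list(
      classifications = classifications,
      counts = counts,
      contingency = contingency,
      provenance = list(
        n_patients = nrow(cohort),
        models = purrr::map_chr(models, "model_id"),
        cohort_hash = rlang::hash(cohort)
      )
    ),
    class = "pra_study"
  )
}

#' @export
print.pra_study <- function(x, ...) {
  cat(sprintf("<pra_study: %d patients, models %s>\n",
              x$provenance$n_patients,
              paste(x$provenance$models, collapse = " vs ")))
  wide <- tidyr::pivot_wider(x$counts, names_from = "category",
                             values_from = "n")
  print(as.data.frame(wide), row.names = FALSE)
  if (!is.null(x$contingency)) {
    cat("\nCross-model agreement:\n")
    print(x$contingency)
  }
  invisible(x)
}

#' Tidy per-patient classifications of a study
#'
#' @param x A `pra_study`.
#' @param ... Unused.
#' @return A tibble with one row per patient per model: `patient_id`,
#'   `model_id`, `n_moderate`, `n_high`, `polygon_area`, `category`.
#' @export
tidy.pra_study <- function(x, ...) {
  dplyr::select(x$classifications, -"scores")
}

#' One-row summary of a study
#'
#' @param x A `pra_study`.
#' @param ... Unused.
#' @return A one-row tibble: `n_patients`, `n_models`, and one
#'   `<model>_<category>` count column per model and category.
#' @export
glance.pra_study <- function(x, ...) {
  counts <- x$counts |>
    dplyr::mutate(key = paste(.data$model_id, .data$category, sep = "_")) |>
    dplyr::select("key", "n") |>
    tidyr::pivot_wider(names_from = "key", values_from = "n")
  dplyr::bind_cols(
    tibble::tibble(n_patients = x$provenance$n_patients,
                   n_models = length(x$provenance$models)),
    counts
  )
}

#' Bar chart of the per-model category distributions
#'
#' @param object A `pra_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pra_study <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(.data$category, .data$n,
                               fill = .data$model_id)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "risk category", y = "patients", fill = "model") +
    ggplot2::theme_minimal()
}

#' Write a study report to JSON (plus a distribution CSV)
#'
#' The JSON report contains the per-model category distributions, the
#' cross-model contingency table, per-patient classification records and
#' the provenance block. A companion CSV of the category distributions is
#' written next to it with suffix `_distribution.csv`.
#'
#' @param study A `pra_study`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(study, path) {
  per_patient <- study$classifications |>
    dplyr::mutate(scores = purrr::map(.data$scores, as.list),
                  category = as.character(.data$category))
  report <- list(
    counts = study$counts |>
      dplyr::mutate(category = as.character(.data$category)),
    contingency = if (!is.null(study$contingency)) {
      list(rows = rownames(study$contingency),
           cols = colnames(study$contingency),
           table = unclass(unname(apply(study$contingency, 1, as.list,
                                        simplify = FALSE))))
    },
    per_patient = per_patient,
    provenance = study$provenance
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  csv_path <- sub("\\.json$", "", path)
  readr::write_csv(
    study$counts |> dplyr::mutate(category = as.character(.data$category)),
    paste0(csv_path, "_distribution.csv"))
  invisible(path)
}
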