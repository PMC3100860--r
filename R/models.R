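#' Construct a periodontal risk assessment model specification
#'
#' Two models are available. `"modified8"` is the eight-parameter model:
#' bleeding on probing, deep pockets (>5 mm), tooth loss, smoking,
#' attachment-loss/age ratio, diabetic status, dental-systemic interplay and
#' socioeconomic/stress background, classified by the completed three-clause
#' counting rule (see [classify_cohort()]). `"lt2003"` is the six-parameter
#' Lang--Tonetti (2003) comparison model over the shared clinical axes,
#' classified by the classic rule. Both models share one coding system, so
#' the same patient record can be assessed under either.
#'
#' @param model_id `"modified8"` or `"lt2003"`.
#' @return An object of class `pra_model`: a list with `model_id`,
#'   `axis_names`, `n_axes` and `rule_id`.
#' @examples
#' pra_model("modified8")$n_axes  # 8
#' pra_model("lt2003")$axis_names
#' @export
pra_model <- function(model_id = c("modified8", "lt2003")) {
  model_id <- rlang::arg_match(model_id)
  spec <- switch(model_id,
    modified8 = list(
      model_id = "modified8",
      axis_names = c("bop", "pockets", "tooth_loss", "smoking", "al_age",
                     "diabetic", "dental_systemic", "background"),
      n_axes = 8L,
      rule_id = "table3_completed"
    ),
    lt2003 = list(
      model_id = "lt2003",
      axis_names = c("bop", "pockets", "tooth_loss", "al_age",
                     "dental_systemic", "smoking"),
      n_axes = 6L,
      rule_id = "lt_classic"
    )
  )
  structure(spec, class = "pra_model")
}

#' Coerce a model id or model spec to a `pra_model`
#' @param x A `pra_model` or a model id string.
#' @return A `pra_model`.
#' @export
as_pra_model <- function(x) {
  if (inherits(x, "pra_model")) return(x)
  if (is.character(x) && length(x) == 1) return(pra_model(x))
  rlang::abort("`model` must be a pra_model or a model id string")
}

#' @export
print.pra_model <- function(x, ...) {
  cat(sprintf("<pra_model %s: %d axes, rule %s>\n  axes: %s\n",
              x$model_id, x$n_axes, x$rule_id,
              paste(x$axis_names, collapse = ", ")))
  invisible(x)
}

#' Risk zone of an axis score
#'
#' The 0--5 score scale splits evenly into the diagram's three concentric
#' zones: scores 0--1 lie in the low annulus, 2--3 in the moderate annulus,
#' 4--5 in the high annulus.
#'
#' @param score Integer axis score(s) in 0--5.
#' @return A factor with levels `low < moderate < high`.
#' @examples
#' risk_zone(0:5)
#' @export
risk_zone <- function(score) {
  if (!is.numeric(score) || anyNA(score) ||
      any(score < 0 | score > 5 | score != round(score))) {
    stop_invalid("score", score, "must be an integer axis score 0-5")
  }
  factor(c("low", "moderate", "high")[score %/% 2 + 1],
         levels = c("low", "moderate", "high"), ordered = TRUE)
}

risk_levels <- c("low", "moderate", "high")

# Counting rules over (m, h) = number of axes in the moderate / high zones.
# table3_completed is the deterministic completion of the printed three
# clauses: the high clause takes precedence, then the low clause, then
# moderate as the residue. lt_classic: at most one non-low axis -> low.
apply_rule <- function(rule_id, m, h) {
  cat_chr <- switch(rule_id,
    table3_completed = dplyr::case_when(
      h >= 2      ~ "high",
      m + h <= 2  ~ "low",
      .default    = "moderate"
    ),
    lt_classic = dplyr::case_when(
      h >= 2      ~ "high",
      m + h <= 1  ~ "low",
      .default    = "moderate"
    ),
    rlang::abort(paste0("unknown rule_id: ", rule_id))
  )
  factor(cat_chr, levels = risk_levels, ordered = TRUE)
}

#' Classify a single axis-score vector
#'
#' Counts the axes falling in the moderate and high zones and applies the
#' model's counting rule. For the modified eight-parameter model the rule is:
#' high risk if at least two axes lie in the high zone; otherwise low risk if
#' at most two axes lie outside the low zone; otherwise moderate. For the
#' Lang--Tonetti model: high if at least two high-zone axes; low if at most
#' one axis lies outside the low zone; otherwise moderate.
#'
#' @param scores Integer vector of axis scores 0--5, one per model axis.
#' @param model A `pra_model` or model id.
#' @return A one-row tibble: `category` (ordered factor low/moderate/high),
#'   `n_moderate`, `n_high`, `polygon_area`.
#' @examples
#' classify_scores(c(5, 5, 0, 0, 0, 0, 0, 0), "modified8")  # high
#' classify_scores(rep(0, 6), "lt2003")                     # low
#' @export
classify_scores <- function(scores, model = "modified8") {
  model <- as_pra_model(model)
  if (length(scores) != model$n_axes) {
    rlang::abort(sprintf(
      "model %s expects %d axis scores, got %d",
      model$model_id, model$n_axes, length(scores)))
  }
  zone <- risk_zone(scores)
  m <- sum(zone == "moderate")
  h <- sum(zone == "high")
  tibble::tibble(
    category = apply_rule(model$rule_id, m, h),
    n_moderate = m,
    n_high = h,
    polygon_area = polygon_area(scores)
  )
}

#' Area of the functional-diagram score polygon
#'
#' The diagram places axis k of n at angle 2*pi*k/n (axis 0 pointing up,
#' proceeding clockwise) with the vertex at radius equal to the raw axis
#' score. The area of the closed polygon is computed by the shoelace
#' formula. A uniform score r on n axes gives the regular-polygon area
#' (n/2) * r^2 * sin(2*pi/n). The area is reported as a diagnostic summary
#' of overall risk burden; categorisation itself uses the counting rules.
#'
#' @param scores Integer vector of axis scores 0--5 (any length >= 3).
#' @return Non-negative polygon area in squared score units.
#' @examples
#' polygon_area(rep(5, 8))  # 4 * 25 * sin(pi/4) = 70.71
#' @export
polygon_area <- function(scores) {
  if (!is.numeric(scores) || anyNA(scores) || length(scores) < 3) {
    stop_invalid("scores", scores, "must be >= 3 numeric axis scores")
  }
  xy <- polygon_vertices(scores)
  j <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(xy$x * xy$y[j] - xy$x[j] * xy$y)) / 2
}

# Cartesian vertices of the score polygon: axis 0 up, clockwise.
polygon_vertices <- function(scores) {
  n <- length(scores)
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  tibble::tibble(x = scores * cos(theta), y = scores * sin(theta))
}

#' Classify every patient in a cohort under one model
#'
#' Scores each record on the model's axes ([score_cohort()]) and applies the
#' model's classification rule, returning one row per patient.
#'
#' @inheritParams score_cohort
#' @return A tibble with `patient_id`, `model_id`, per-axis scores as a
#'   list-column `scores` (named integer vectors), `n_moderate`, `n_high`
#'   (counts of axes in those zones), `polygon_area` and `category`
#'   (ordered factor low/moderate/high).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5))
#' classify_cohort(cohort, "lt2003")
#' @export
classify_cohort <- function(cohort, model = "modified8") {
  model <- as_pra_model(model)
  long <- score_cohort(cohort, model)
  long |>
    dplyr::summarise(
      scores = list(rlang::set_names(.data$score, as.character(.data$axis))),
      n_moderate = sum(.data$zone == "moderate"),
      n_high = sum(.data$zone == "high"),
      polygon_area = polygon_area(.data$score),
      .by = "patient_id"
    ) |>
    dplyr::mutate(
      model_id = model$model_id, .after = "patient_id"
    ) |>
    dplyr::mutate(
      category = apply_rule(model$rule_id, .data$n_moderate, .data$n_high)
    )
}

#' Serialise per-patient classifications to JSON records
#'
#' Writes one JSON record per patient with `patient_id`, `model_id`,
#' per-axis scores and zones, the moderate/high axis counts, the polygon
#' area and the category.
#'
#' @param classified Output of [classify_cohort()].
#' @param path File path for the JSON output.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(classified, path) {
  records <- purrr::pmap(classified, function(patient_id, model_id, scores,
                                              n_moderate, n_high,
                                              polygon_area, category) {
    list(
      patient_id = patient_id,
      model_id = model_id,
      scores = as.list(scores),
      zones = as.list(rlang::set_names(as.character(risk_zone(scores)),
                                       names(scores))),
      n_moderate = n_moderate,
      n_high = n_high,
      polygon_area = polygon_area,
      category = as.character(category)
    )
  })
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
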