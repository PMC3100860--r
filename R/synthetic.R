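#' Configuration for the synthetic cohort generator
#'
#' The defaults encode the study conditions of the evaluated cohort: 30
#' diabetic adults aged 30--60, all with generalized bleeding on probing,
#' 12 current and 4 former smokers, 15 patients (50%) with deep pockets at
#' 7--8 areas and 10 (35% rounded to the nearest feasible count) at 5--6
#' areas, 14 (47%) with an attachment-loss/age ratio in (0.25, 0.75] and 3
#' (10%) above 1, 10 (35%) with 7--8 missing teeth, and socioeconomic status
#' concentrated in the Kuppuswamy lower-middle (IV) and lower (V) classes.
#' Category counts are met exactly on every run; everything else is drawn
#' from seeded distributions over the band's valid range.
#'
#' @param n_patients Cohort size.
#' @param n_current_smokers,n_former_smokers Exact smoker counts.
#' @param n_pockets_high Patients with 7--8 deep-pocket areas.
#' @param n_pockets_mid Patients with 5--6 deep-pocket areas.
#' @param n_loa_moderate Patients with attachment-loss/age ratio in
#'   (0.25, 0.75].
#' @param n_loa_severe Patients with attachment-loss/age ratio > 1.
#' @param n_toothloss_78 Patients with 7--8 missing teeth.
#' @param ses_weights Named sampling weights over Kuppuswamy classes I--V.
#' @param all_generalized_bop If `TRUE`, every patient bleeds at >25% of
#'   sites (generalized bleeding on probing).
#' @param all_diabetic If `TRUE`, every glycemic value is at least
#'   110 mg/dL (established banded elevation).
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A `cohort_config` list.
#' @examples
#' cfg <- cohort_config()
#' cfg$n_current_smokers  # 12
#' @export
cohort_config <- function(n_patients = 30,
                          n_current_smokers = 12,
                          n_former_smokers = 4,
                          n_pockets_high = 15,
                          n_pockets_mid = 10,
                          n_loa_moderate = 14,
                          n_loa_severe = 3,
                          n_toothloss_78 = 10,
                          ses_weights = c(I = 0.02, II = 0.05, III = 0.13,
                                          IV = 0.45, V = 0.35),
                          all_generalized_bop = TRUE,
                          all_diabetic = TRUE,
                          seed = 42) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_current_smokers = as.integer(n_current_smokers),
    n_former_smokers = as.integer(n_former_smokers),
    n_pockets_high = as.integer(n_pockets_high),
    n_pockets_mid = as.integer(n_pockets_mid),
    n_loa_moderate = as.integer(n_loa_moderate),
    n_loa_severe = as.integer(n_loa_severe),
    n_toothloss_78 = as.integer(n_toothloss_78),
    ses_weights = ses_weights,
    all_generalized_bop = isTRUE(all_generalized_bop),
    all_diabetic = isTRUE(all_diabetic),
    seed = as.integer(seed)
  )
  n <- cfg$n_patients
  if (is.na(n) || n < 1) stop_invalid("n_patients", n_patients, "must be >= 1")
  counts <- cfg[grep("^n_", names(cfg))]
  over <- vapply(counts[-1], function(k) is.na(k) || k < 0 || k > n, logical(1))
  if (any(over)) {
    stop_invalid(names(counts[-1])[over][1], counts[-1][over][[1]],
                 sprintf("must be a count between 0 and n_patients (%d)", n))
  }
  if (cfg$n_current_smokers + cfg$n_former_smokers > n) {
    stop_invalid("n_current_smokers", cfg$n_current_smokers,
                 "smoker counts must sum to at most n_patients")
  }
  if (cfg$n_pockets_high + cfg$n_pockets_mid > n) {
    stop_invalid("n_pockets_high", cfg$n_pockets_high,
                 "pocket-band counts must sum to at most n_patients")
  }
  if (cfg$n_loa_moderate + cfg$n_loa_severe > n) {
    stop_invalid("n_loa_moderate", cfg$n_loa_moderate,
                 "attachment-loss band counts must sum to at most n_patients")
  }
  if (!is.numeric(ses_weights) || length(ses_weights) != 5 ||
      !identical(names(ses_weights), c("I", "II", "III", "IV", "V")) ||
      any(ses_weights < 0) || sum(ses_weights) <= 0) {
    stop_invalid("ses_weights", ses_weights,
                 "must be non-negative weights named I-V")
  }
  structure(cfg, class = "cohort_config")
}

#' Read a cohort configuration from YAML or JSON
#'
#' Field names must match the arguments of [cohort_config()]; unknown fields
#' are an error. Omitted fields take their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), names(formals(cohort_config)))
  if (length(unknown)) {
    rlang::abort(paste0("unknown config fields: ",
                        paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$ses_weights)) raw$ses_weights <- unlist(raw$ses_weights)
  do.call(cohort_config, raw)
}

# Run expr with the RNG seeded from `seed`, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Exact-count band assignment: labels per band, shuffled.
shuffled_bands <- function(n, counts) {
  labels <- rep(seq_len(length(counts) + 1L) - 1L,
                times = c(counts, n - sum(counts)))
  sample(labels, n)
}

#' Generate a seeded synthetic patient cohort
#'
#' Produces exactly `n_patients` records satisfying every record invariant.
#' Band memberships with configured counts (smoking status, deep-pocket
#' band, tooth-loss band, attachment-loss band) are assigned exactly by
#' deterministic label construction followed by a seeded shuffle; the joint
#' structure across bands is independent, since no correlation structure is
#' asserted for the cohort being emulated. Continuous values are drawn
#' uniformly within each band's valid range, and the whole cohort is a pure
#' function of the configuration (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A tibble of patient records (one row per patient) with the
#'   columns listed in [score_cohort()].
#' @examples
#' cohort <- generate_cohort(cohort_config())
#' table(cohort$smoking_status)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  n <- config$n_patients
  with_local_seed(config$seed, {
    smoking_band <- shuffled_bands(
      n, c(config$n_current_smokers, config$n_former_smokers))
    smoking_status <- c("current", "former", "nonsmoker")[smoking_band + 1L]
    cigarettes_per_day <- ifelse(
      smoking_status == "current",
      sample(1:25, n, replace = TRUE),
      NA_integer_
    )

    pocket_band <- shuffled_bands(
      n, c(config$n_pockets_high, config$n_pockets_mid))
    pockets_over_5mm <- dplyr::case_when(
      pocket_band == 0 ~ sample(7:8, n, replace = TRUE),
      pocket_band == 1 ~ sample(5:6, n, replace = TRUE),
      .default         = sample(0:4, n, replace = TRUE)
    )

    loa_band <- shuffled_bands(
      n, c(config$n_loa_severe, config$n_loa_moderate))
    al_age_ratio <- round(dplyr::case_when(
      loa_band == 0 ~ stats::runif(n, 1.01, 1.5),
      loa_band == 1 ~ stats::runif(n, 0.26, 0.75),
      .default      = stats::runif(n, 0.01, 0.25)
    ), 3)

    tooth_band <- shuffled_bands(n, config$n_toothloss_78)
    teeth_lost <- ifelse(tooth_band == 0,
                         sample(7:8, n, replace = TRUE),
                         sample(0:6, n, replace = TRUE))

    bop_extent <- round(if (config$all_generalized_bop) {
      stats::runif(n, 26, 95)
    } else {
      stats::runif(n, 0, 95)
    }, 1)

    glycemic_value <- round(if (config$all_diabetic) {
      stats::runif(n, 110, 160)
    } else {
      stats::runif(n, 85, 160)
    }, 1)

    tibble::tibble(
      patient_id = sprintf("P%02d", seq_len(n)),
      age = sample(30:60, n, replace = TRUE),
      bop_extent = bop_extent,
      pockets_over_5mm = as.integer(pockets_over_5mm),
      teeth_lost = as.integer(teeth_lost),
      smoking_status = smoking_status,
      cigarettes_per_day = as.integer(cigarettes_per_day),
      al_age_ratio = al_age_ratio,
      glycemic_value = glycemic_value,
      dental_systemic_status = sample(0:3, n, replace = TRUE,
                                      prob = c(0.35, 0.3, 0.2, 0.15)),
      ses_class = sample(names(config$ses_weights), n, replace = TRUE,
                         prob = config$ses_weights),
      high_stress = stats::runif(n) < 0.4
    )
  })
}
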