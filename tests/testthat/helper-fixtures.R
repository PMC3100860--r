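# Patient-record fixtures built in code.

# A fully healthy-anchor record; override any field by name.
make_record <- function(..., patient_id = "P01") {
  rec <- tibble::tibble(
    patient_id = patient_id,
    age = 40L,
    bop_extent = 0,
    pockets_over_5mm = 0L,
    teeth_lost = 0L,
    smoking_status = "nonsmoker",
    cigarettes_per_day = NA_integer_,
    al_age_ratio = 0,
    glycemic_value = 95,
    dental_systemic_status = 0L,
    ses_class = "I",
    high_stress = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  rec
}

# Plain re-implementation of the zone lookup and counting rules, written
# directly from the rule clauses, used as the independent oracle against
# the package's classifier.
oracle_zone <- function(score) c("low", "low", "moderate", "moderate",
                                 "high", "high")[score + 1]

oracle_classify <- function(scores, rule) {
  z <- oracle_zone(scores)
  m <- sum(z == "moderate")
  h <- sum(z == "high")
  if (rule == "table3_completed") {
    if (h >= 2) "high" else if (m + h <= 2) "low" else "moderate"
  } else {
    if (h >= 2) "high" else if (m + h <= 1) "low" else "moderate"
  }
}

category_rank <- function(x) match(as.character(x), c("low", "moderate", "high"))
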