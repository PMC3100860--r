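Package: periorisk
Title: Multi-Axis Periodontal Risk Assessment Scoring and Functional Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores adult periodontal patients on banded clinical axes
    (bleeding on probing, deep pockets, tooth loss, smoking, attachment
    loss to age ratio, glycemic status, dental-systemic interplay and
    socioeconomic background), classifies them into low, moderate and
    high risk under an eight-parameter periodontal risk assessment model
    and the six-parameter Lang-Tonetti (2003) comparison model, renders
    the functional diagram (radar chart with demarcated risk zones), and
    generates seeded synthetic cohorts with fixed marginal counts so the
    full model-comparison pipeline can be exercised and audited without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
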