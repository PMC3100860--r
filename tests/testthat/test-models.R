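test_that("model specs fix the axis lists and rules", {
  m8 <- pra_model("modified8")
  lt <- pra_model("lt2003")
  expect_identical(m8$n_axes, 8L)
  expect_identical(lt$n_axes, 6L)
  expect_identical(lt$axis_names,
                   c("bop", "pockets", "tooth_loss", "al_age",
                     "dental_systemic", "smoking"))
  expect_setequal(setdiff(m8$axis_names, lt$axis_names),
                  c("diabetic", "background"))
  expect_error(pra_model("lt1997"))
  expect_error(as_pra_model(42), "pra_model")
})

test_that("risk zones split the score scale 0-1 / 2-3 / 4-5", {
  expect_identical(as.character(risk_zone(0:5)),
                   c("low", "low", "moderate", "moderate", "high", "high"))
  expect_error(risk_zone(6), "score")
  expect_error(risk_zone(2.5), "score")
})

test_that("printed rule clauses classify as stated", {
  # all parameters in low risk areas -> low
  expect_identical(as.character(classify_scores(rep(0, 8))$category), "low")
  # at most 2 parameters outside the low area -> low
  expect_identical(as.character(classify_scores(c(3, 2, 0, 0, 0, 0, 0, 0))$category),
                   "low")
  # 3 in moderate, one in high -> moderate
  expect_identical(as.character(classify_scores(c(2, 2, 2, 4, 0, 0, 0, 0))$category),
                   "moderate")
  # 2 parameters in the high category -> high
  expect_identical(as.character(classify_scores(c(5, 5, 0, 0, 0, 0, 0, 0))$category),
                   "high")
  # comparison model: a single non-low axis is still low, two high axes high
  expect_identical(as.character(classify_scores(c(2, 0, 0, 0, 0, 0), "lt2003")$category),
                   "low")
  expect_identical(as.character(classify_scores(c(2, 2, 0, 0, 0, 0), "lt2003")$category),
                   "moderate")
  expect_identical(as.character(classify_scores(c(4, 5, 0, 0, 0, 0), "lt2003")$category),
                   "high")
  expect_error(classify_scores(rep(0, 6), "modified8"), "8 axis scores")
})

test_that("classification is total, exclusive and matches the oracle by enumeration", {
  # exhaustive over all 6^6 six-axis vectors
  g6 <- as.matrix(expand.grid(rep(list(0:5), 6)))
  m <- rowSums(g6 >= 2 & g6 <= 3)
  h <- rowSums(g6 >= 4)
  got_lt <- ifelse(h >= 2, "high", ifelse(m + h <= 1, "low", "moderate"))
  idx <- withr::with_seed(7, sample.int(nrow(g6), 300))
  for (i in idx) {
    res <- classify_scores(g6[i, ], "lt2003")
    expect_identical(as.character(res$category),
                     oracle_classify(g6[i, ], "lt_classic"))
    expect_identical(as.character(res$category), got_lt[i])
  }
  # every vector gets exactly one of the three categories
  expect_identical(sum(got_lt %in% c("low", "moderate", "high")), nrow(g6))

  # exhaustive over all 6^8 eight-axis vectors, vectorised zone counting
  g8 <- as.matrix(expand.grid(rep(list(0:5), 8)))
  m8 <- rowSums(g8 >= 2 & g8 <= 3)
  h8 <- rowSums(g8 >= 4)
  n_high <- sum(h8 >= 2)
  n_low <- sum(h8 < 2 & m8 + h8 <= 2)
  n_mod <- sum(h8 < 2 & m8 + h8 > 2)
  expect_identical(n_high + n_low + n_mod, nrow(g8))  # total and exclusive
  # spot-check the classifier against the enumeration and the oracle
  idx8 <- withr::with_seed(8, sample.int(nrow(g8), 300))
  enum_cat <- ifelse(h8 >= 2, "high", ifelse(m8 + h8 <= 2, "low", "moderate"))
  for (i in idx8) {
    res <- classify_scores(g8[i, ], "modified8")
    expect_identical(as.character(res$category), enum_cat[i])
    expect_identical(as.character(res$category),
                     oracle_classify(g8[i, ], "table3_completed"))
    expect_identical(res$n_moderate, as.integer(m8[i]))
    expect_identical(res$n_high, as.integer(h8[i]))
  }
})

test_that("raising any single axis score never lowers the category", {
  withr::with_seed(20260927, {
    for (model in c("modified8", "lt2003")) {
      n <- pra_model(model)$n_axes
      for (rep in 1:400) {
        v <- sample(0:5, n, replace = TRUE)
        k <- sample.int(n, 1)
        if (v[k] == 5) next
        v2 <- v
        v2[k] <- v[k] + 1
        r1 <- category_rank(classify_scores(v, model)$category)
        r2 <- category_rank(classify_scores(v2, model)$category)
        expect_gte(r2, r1)
      }
    }
  })
})

test_that("category depends only on the multiset of axis scores", {
  withr::with_seed(1, {
    for (rep in 1:100) {
      v <- sample(0:5, 8, replace = TRUE)
      p <- sample(v)
      expect_identical(classify_scores(v)$category, classify_scores(p)$category)
    }
  })
})

test_that("polygon area matches the regular-polygon closed form", {
  for (n in c(6L, 8L)) {
    for (r in 0:5) {
      expect_equal(polygon_area(rep(r, n)), (n / 2) * r^2 * sin(2 * pi / n),
                   tolerance = 1e-9)
    }
  }
  expect_identical(polygon_area(rep(0, 8)), 0)
  expect_error(polygon_area(c(1, 2)), "scores")
})

test_that("polygon area is non-decreasing in every coordinate", {
  withr::with_seed(99, {
    for (rep in 1:500) {
      n <- sample(c(6L, 8L), 1)
      v <- sample(0:5, n, replace = TRUE)
      k <- sample.int(n, 1)
      if (v[k] == 5) next
      v2 <- v
      v2[k] <- v[k] + 1
      expect_gte(polygon_area(v2), polygon_area(v))
    }
  })
})

test_that("figure-caption patients classify as their figures state", {
  # low-risk figure: generalized bleeding, probing depth only 3-4 mm
  fig2 <- c(5, 2, 0, 0, 0, 0, 0, 0)
  expect_identical(as.character(classify_scores(fig2, "modified8")$category),
                   "low")
  # high-risk figure: generalized bleeding, pockets beyond 8 mm, 10-19/day
  fig4_rec <- make_record(bop_extent = 50, pockets_over_5mm = 9L,
                          smoking_status = "current",
                          cigarettes_per_day = 15L)
  cls <- classify_cohort(fig4_rec, "modified8")
  expect_gte(cls$n_high, 2L)
  expect_identical(as.character(cls$category), "high")
  # the healthy anchor is low under both models
  for (model in c("modified8", "lt2003")) {
    expect_identical(as.character(classify_cohort(make_record(), model)$category),
                     "low")
  }
})

test_that("classification JSON records carry scores, zones, counts and area", {
  path <- withr::local_tempfile(fileext = ".json")
  classified <- classify_cohort(
    make_record(bop_extent = 50, pockets_over_5mm = 9L), "modified8")
  write_classification_json(classified, path)
  rec <- jsonlite::read_json(path)[[1]]
  expect_identical(rec$patient_id, "P01")
  expect_identical(rec$model_id, "modified8")
  expect_identical(rec$scores$bop, 5L)
  expect_identical(rec$zones$pockets, "high")
  expect_identical(rec$n_high, 2L)
  expect_identical(rec$category, "high")
  expect_equal(rec$polygon_area, polygon_area(c(5, 5, 0, 0, 0, 0, 0, 0)))
})
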