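# Document construction guards, validation, navigation, self-containment.

test_that("a new document is empty, valid and uniquely identified", {
  d1 <- dnmso_document(creator = "test")
  expect_length(d1$spectra, 0)
  expect_length(d1$predictions, 0)
  expect_equal(nrow(validate_document(d1)), 0)
  d2 <- dnmso_document(creator = "test")
  expect_false(identical(d1$id, d2$id))
})

test_that("spectra round-trip through add_spectrum with guarded invariants", {
  doc <- dnmso_document("t") |>
    add_spectrum(spectrum(500.25, 2, peaks = three_peaks(), id = "s1"))
  expect_equal(nrow(doc$spectra$s1$peaks), 3)
  expect_error(add_spectrum(doc, spectrum(500, 2, peaks = three_peaks(), id = "s1")),
               "identity-conflict")
  expect_error(
    spectrum(500, 2, peaks = data.frame(mz = c(300, 100), intensity = c(1, 1))),
    "sorted")
  # external-ref-only spectra (no peaks) are accepted
  doc2 <- add_spectrum(doc, spectrum(
    601.1, 2, external_ref = external_ref("run.mzML", "mzML", "scan=9")))
  expect_equal(nrow(validate_document(doc2)), 0)
  # a spectrum needs peaks or a reference; charge must be positive or NA
  expect_error(spectrum(500, 2), "external reference")
  expect_error(spectrum(500, 0, peaks = three_peaks()), "positive")
  expect_error(spectrum(-1, 2, peaks = three_peaks()), "precursor_mz")
  expect_error(external_ref("f", "MGF", ""), "native_id")
})

test_that("prediction guards enforce scores, sources and resolvable refs", {
  doc <- dnmso_document("t") |>
    add_spectrum(spectrum(500, 2, peaks = three_peaks(), id = "s1"))
  doc <- add_prediction(doc, prediction(pep_sequence("PEP"),
                                        score("X", 1), "s1"))
  expect_length(doc$predictions, 1)
  expect_error(prediction(pep_sequence("PEP"), list(), "s1"), "missing-score")
  expect_error(prediction(pep_sequence("PEP"), score("X", 1), character(0)),
               "orphan-prediction")
  expect_error(add_prediction(doc, prediction(pep_sequence("PEP"),
                                              score("X", 1), "s99")),
               "unresolved-reference")
  expect_error(add_prediction(doc, prediction(
    pep_sequence(mod_aa("S", "MOD:00046")), score("X", 1), "s1")),
    "unresolved-reference")
})

test_that("a prediction may be sourced from several spectra (CID + ETD)", {
  doc <- dnmso_document("t") |>
    add_spectrum(spectrum(500, 2, peaks = three_peaks(), id = "cid",
                          fragmentation = "CID")) |>
    add_spectrum(spectrum(500, 2, peaks = three_peaks(), id = "etd",
                          fragmentation = "ETD")) |>
    add_prediction(prediction(pep_sequence("PEP"), score("X", 1),
                              c("cid", "etd"), id = "p"))
  expect_equal(nrow(validate_document(doc)), 0)
  expect_equal(names(predictions_for_spectrum(doc, "cid")), "p")
  expect_equal(names(predictions_for_spectrum(doc, "etd")), "p")
})

test_that("many-to-many navigation matches a brute-force scan (seeded)", {
  doc <- random_document(11, 8, 50)
  for (sid in names(doc$spectra)) {
    got <- names(predictions_for_spectrum(doc, sid))
    brute <- names(Filter(function(p) sid %in% p$source_spectrum_refs,
                          doc$predictions))
    expect_identical(got, brute)
  }
  # involution: s in p$refs <=> p in predictions_for_spectrum(s)
  for (pid in names(doc$predictions)) {
    for (sid in doc$predictions[[pid]]$source_spectrum_refs) {
      expect_true(pid %in% names(predictions_for_spectrum(doc, sid)))
    }
  }
  expect_error(predictions_for_spectrum(doc, "nope"), "unresolved-reference")
})

test_that("orphan spectra are permitted; orphan predictions are not", {
  doc <- dnmso_document("t") |>
    add_spectrum(spectrum(500, 2, peaks = three_peaks(), id = "used")) |>
    add_spectrum(spectrum(700, 3, peaks = three_peaks(), id = "orphan")) |>
    add_prediction(prediction(pep_sequence("PEP"), score("X", 1), "used"))
  expect_equal(nrow(validate_document(doc)), 0)
  expect_length(predictions_for_spectrum(doc, "orphan"), 0)
  doc$predictions[[1]]$source_spectrum_refs <- character(0)
  v <- validate_document(doc)
  expect_true("orphan_prediction" %in% v$rule)
})

test_that("every injected defect is flagged with its rule; clean twin is not", {
  cat <- defect_catalogue()
  expect_equal(nrow(validate_document(cat$clean)), 0)
  for (rule in names(cat$defects)) {
    v <- validate_document(cat$defects[[rule]])
    expect_true(rule %in% v$rule, info = rule)
    expect_true(all(v$severity[v$rule == rule] == "ERROR"), info = rule)
    # the violation names the defective element
    expect_true(all(nzchar(v$element)), info = rule)
  }
})

test_that("violations are returned ordered by element id, not raised", {
  cat <- defect_catalogue()
  d <- cat$defects$dangling_spectrum_ref
  d$spectra$s2$peaks <- data.frame(mz = c(5, 1), intensity = c(1, 1))
  v <- validate_document(d)
  expect_identical(v$element, sort(v$element))
  expect_s3_class(v, "tbl_df")
})

test_that("self-containment looks only at prediction-referenced spectra", {
  doc <- small_doc()
  expect_true(is_self_contained(doc))
  # an orphan external-ref spectrum does not break self-containment
  doc2 <- add_spectrum(doc, spectrum(
    800, 2, external_ref = external_ref("raw.mzML", "mzML", "scan=3"),
    id = "ext_orphan"))
  sc <- is_self_contained(doc2)
  expect_true(sc)
  expect_length(attr(sc, "external_refs"), 0)
  # ...but a prediction sourced from it does
  doc3 <- add_prediction(doc2, prediction(pep_sequence("AG"), score("X", 1),
                                          "ext_orphan"))
  sc3 <- is_self_contained(doc3)
  expect_false(sc3)
  expect_equal(attr(sc3, "external_refs"), "ext_orphan")
})

test_that("auto-generated ids are deterministic and collision-free", {
  doc <- dnmso_document("t")
  doc <- add_spectrum(doc, spectrum(1, 1, peaks = three_peaks()))
  expect_equal(attr(doc, "last_id"), "SPEC_1")
  doc <- add_spectrum(doc, spectrum(2, 1, peaks = three_peaks(), id = "SPEC_2"))
  doc <- add_spectrum(doc, spectrum(3, 1, peaks = three_peaks()))
  expect_equal(attr(doc, "last_id"), "SPEC_3") # skips the taken id
  doc <- add_prediction(doc, prediction(pep_sequence("AG"), score("X", 1), "SPEC_1"))
  expect_equal(attr(doc, "last_id"), "PRED_1")
})

test_that("tidy and glance summarize predictions and document state", {
  doc <- small_doc()
  td <- tidy(doc)
  expect_equal(nrow(td), 2)
  expect_true(all(c("prediction", "sequence", "rank", "score_RnkScr") %in% names(td)))
  expect_equal(td$n_spectra, c(1L, 2L))
  g <- glance(doc)
  expect_equal(g$n_spectra, 2L)
  expect_equal(g$n_predictions, 2L)
  expect_true(g$self_contained)
  expect_equal(g$n_violations, 0L)
})
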