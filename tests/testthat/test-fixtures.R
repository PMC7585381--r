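# The synthetic-data generator: determinism, internal consistency, and the
# full-stack recovery property.

test_that("generation is deterministic for a fixed seed", {
  a <- generate_ground_truth(fixture_spec(seed = 42, n_spectra = 5))
  b <- generate_ground_truth(fixture_spec(seed = 42, n_spectra = 5))
  expect_identical(
    lapply(a$records, function(r) r$spectrum$peaks),
    lapply(b$records, function(r) r$spectrum$peaks))
  expect_identical(
    vapply(a$records, function(r) render_sequence(r$sequence), character(1)),
    vapply(b$records, function(r) render_sequence(r$sequence), character(1)))
  c <- generate_ground_truth(fixture_spec(seed = 43, n_spectra = 5))
  expect_false(identical(
    vapply(a$records, function(r) render_sequence(r$sequence), character(1)),
    vapply(c$records, function(r) render_sequence(r$sequence), character(1))))
})

test_that("precursor neutral mass matches the peptide mass to 1e-9 relative", {
  truth <- generate_ground_truth(fixture_spec(seed = 44, n_spectra = 20,
                                              modification_rate = 0.5))
  for (r in truth$records) {
    m <- sequence_mono_mass(r$sequence, truth$modifications)
    expect_equal(precursor_neutral_mass(r$spectrum$precursor_mz, 2), m,
                 tolerance = 1e-9)
  }
})

test_that("b/y fragment m/z values match the hand-summed oracle", {
  # peptide AG at charge 1: y1 = G residue + water + proton
  fr <- fragment_ions(pep_sequence("AG"))
  y1 <- fr$mz[fr$ion == "y1"]
  expect_equal(y1, oracle_residue_mass("G") + ORACLE_WATER + 1.007276,
               tolerance = 1e-5)
  b1 <- fr$mz[fr$ion == "b1"]
  expect_equal(b1, oracle_residue_mass("A") + 1.007276, tolerance = 1e-5)
  # every true fragment is present in the generated spectrum
  truth <- generate_ground_truth(fixture_spec(seed = 45, n_spectra = 3))
  for (r in truth$records) {
    fr <- fragment_ions(r$sequence, truth$modifications)
    expect_true(all(vapply(fr$mz, function(m) {
      any(abs(r$spectrum$peaks$mz - m) < 1e-9)
    }, logical(1))))
  }
})

test_that("tool outputs parse back with zero skipped records", {
  fx <- fixture_spec(seed = 46, n_spectra = 5)
  truth <- generate_ground_truth(fx)
  d <- withr::local_tempdir()
  paths <- write_tool_outputs(truth, fx, d)
  expect_equal(convert_pepxml(paths$pepxml, paths$mgf)$report$skipped, 0L)
  expect_equal(convert_pepnovo(paths$pepnovo, paths$mgf)$report$skipped, 0L)
  expect_equal(convert_lutefisk(paths$lutefisk, paths$mgf)$report$skipped, 0L)
  expect_equal(convert_dnml(paths$dnml)$report$skipped, 0L)
})

test_that("generated files exercise every dialect field", {
  fx <- fixture_spec(seed = 47, n_spectra = 8, modification_rate = 0.8,
                     gap_rate = 0.9)
  truth <- generate_ground_truth(fx)
  d <- withr::local_tempdir()
  paths <- write_tool_outputs(truth, fx, d)
  pn <- convert_pepnovo(paths$pepnovo, paths$mgf)$document
  lf <- convert_lutefisk(paths$lutefisk, paths$mgf)$document
  dn <- convert_dnml(paths$dnml)$document
  px <- convert_pepxml(paths$pepxml, paths$mgf)$document
  has_kind <- function(doc, kind) any(vapply(doc$predictions, function(p) {
    any(vapply(p$sequence$elements, function(e) e$kind == kind, logical(1)))
  }, logical(1)))
  # gaps in the gap-capable dialects, modifications everywhere, multi-score
  expect_true(has_kind(lf, "gap"))
  expect_true(has_kind(dn, "gap"))
  expect_true(has_kind(pn, "mod_aa"))
  expect_true(has_kind(px, "mod_aa"))
  expect_true(all(vapply(pn$predictions, function(p) length(p$scores) == 2,
                         logical(1))))
  expect_true(any(vapply(pn$predictions, function(p) (p$rank %||% 1) > 1,
                         logical(1))))
})

test_that("full agreement is recovered end to end; forced disagreement is not", {
  fx <- fixture_spec(seed = 48, n_spectra = 8, agreement_profile = 1.0)
  truth <- generate_ground_truth(fx)
  d <- withr::local_tempdir()
  paths <- write_tool_outputs(truth, fx, d)
  docs <- list(convert_pepnovo(paths$pepnovo, paths$mgf)$document,
               convert_lutefisk(paths$lutefisk, paths$mgf)$document,
               convert_dnml(paths$dnml)$document)
  cons <- suppressWarnings(consensus(docs, consensus_params(min_agreement = 3)))
  truth_txt <- vapply(truth$records,
                      function(r) render_sequence(r$sequence, "annotated",
                                                  truth$modifications),
                      character(1))
  got <- vapply(cons$predictions,
                function(p) render_sequence(p$sequence, "annotated",
                                            cons$modifications),
                character(1))
  expect_equal(sort(unname(got)), sort(unname(truth_txt)))

  fx0 <- fixture_spec(seed = 49, n_spectra = 8, agreement_profile = 0.0)
  t0 <- generate_ground_truth(fx0)
  d0 <- withr::local_tempdir()
  p0 <- write_tool_outputs(t0, fx0, d0)
  docs0 <- list(convert_pepnovo(p0$pepnovo, p0$mgf)$document,
                convert_lutefisk(p0$lutefisk, p0$mgf)$document,
                convert_dnml(p0$dnml)$document)
  cons0 <- suppressWarnings(consensus(docs0, consensus_params(min_agreement = 3)))
  expect_length(cons0$predictions, 0)
})

test_that("random_document is deterministic and always valid", {
  expect_true(semantic_equal(random_document(3), random_document(3)))
  for (seed in 10:14) {
    expect_equal(nrow(validate_document(random_document(seed))), 0)
  }
})
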