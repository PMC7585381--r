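# Legacy-format converters and the mzIdentML exporter.

fixture_paths <- function(seed = 42, n = 6, ...) {
  fx <- fixture_spec(seed = seed, n_spectra = n, ...)
  truth <- generate_ground_truth(fx)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_tool_outputs(truth, fx, dir)
  list(fx = fx, truth = truth, paths = paths)
}

test_that("PepNovo conversion preserves ranks, scores and N-/C-gaps", {
  f <- tempfile()
  mgf <- tempfile(fileext = ".mgf")
  write_mgf(list(spectrum(500.25, 2, peaks = three_peaks(), native_id = "scanA")),
            mgf)
  writeLines(c(
    ">> 0 scanA",
    paste(dnmso:::PEPNOVO_HEADER, collapse = "\t"),
    paste(c("0", "1.234", "45.6", "0.000", "100.000", "800.432", "2", "AG"),
          collapse = "\t"),
    paste(c("1", "0.934", "33.1", "0.000", "0.000", "800.432", "2", "AGPK"),
          collapse = "\t")), f)
  res <- convert_pepnovo(f, mgf)
  expect_length(res$document$predictions, 2)
  p1 <- res$document$predictions[[1]]
  expect_equal(p1$rank, 1L)
  expect_equal(vapply(p1$scores, `[[`, character(1), "name"),
               c("RnkScr", "PnvScr"))
  # C-gap of 100 Da becomes a trailing gap element
  kinds <- vapply(p1$sequence$elements, `[[`, character(1), "kind")
  expect_identical(kinds, c("aa", "aa", "gap"))
  expect_equal(p1$sequence$elements[[3]]$mass, 100)
  expect_equal(res$report$predictions_converted, 2L)
  expect_equal(nrow(validate_document(res$document)), 0)
})

test_that("PepNovo rejects unknown layouts and unmatched spectra loudly", {
  mgf <- tempfile(fileext = ".mgf")
  write_mgf(list(spectrum(500, 2, peaks = three_peaks(), native_id = "scanA")), mgf)
  f <- tempfile()
  writeLines(c(">> 0 scanA", "#Idx\tScore\tSeq", "0\t1\tAG"), f)
  expect_error(convert_pepnovo(f, mgf), "dialect error")
  writeLines(c(">> 5 not_present",
               paste(dnmso:::PEPNOVO_HEADER, collapse = "\t"),
               paste(c("0", "1", "1", "0", "0", "123.0", "2", "AG"),
                     collapse = "\t")), f)
  expect_error(convert_pepnovo(f, mgf), "unresolved-spectrum")
  expect_error(convert_pepnovo(tempfile(), list()), "requires companion spectra")
})

test_that("Lutefisk rows carry two named scores and bracketed gaps", {
  mgf <- tempfile(fileext = ".mgf")
  write_mgf(list(spectrum(500, 2, peaks = three_peaks(), native_id = "scanA")), mgf)
  f <- tempfile()
  writeLines(c("Spectrum: scanA",
               paste(dnmso:::LUTEFISK_HEADER, collapse = "\t"),
               paste(c("1", "0.950", "0.880", "[100.000]AG"), collapse = "\t")), f)
  res <- convert_lutefisk(f, mgf)
  p <- res$document$predictions[[1]]
  expect_equal(vapply(p$scores, `[[`, character(1), "name"),
               c("Pr(c)", "Quality"))
  expect_equal(p$sequence$elements[[1]]$kind, "gap")
  expect_equal(p$sequence$elements[[1]]$mass, 100)
  # empty results file -> empty document, 0 records
  empty <- tempfile(); writeLines(character(0), empty)
  res0 <- convert_lutefisk(empty, mgf)
  expect_length(res0$document$predictions, 0)
  expect_equal(res0$report$records_seen, 0L)
})

test_that("DNML conversion keeps the single score, links and mod table", {
  p <- fixture_paths(seed = 19, n = 4, modification_rate = 0.9)
  res <- convert_dnml(p$paths$dnml)
  expect_equal(length(res$document$predictions),
               4 * p$fx$candidates_per_spectrum)
  expect_true(all(vapply(res$document$predictions,
                         function(q) length(q$scores) == 1, logical(1))))
  expect_equal(res$report$skipped, 0L)
  expect_match(res$report$lossiness, "merged-spectra")
  expect_equal(nrow(validate_document(res$document)), 0)
})

test_that("DNML results with two source spectra keep both links", {
  f <- tempfile(fileext = ".xml")
  writeLines(paste0(
    '<dnml version="1.0"><spectra>',
    '<spectrum id="cid" precursorMz="500" charge="2"><peaks>100:1 200:2</peaks></spectrum>',
    '<spectrum id="etd" precursorMz="500" charge="2"><peaks>100:1 200:2</peaks></spectrum>',
    '</spectra><predictions>',
    '<prediction id="p" spectrumRefs="cid etd" score="0.9"><sequence>AG</sequence></prediction>',
    '</predictions></dnml>'), f)
  res <- convert_dnml(f)
  expect_equal(res$document$predictions$p$source_spectrum_refs, c("cid", "etd"))
})

test_that("DNMSO -> DNML -> DNMSO preserves the DNML-expressible subset", {
  doc <- dnmso_document("t", id = "SUB") |>
    add_spectrum(spectrum(500.25, 2, peaks = three_peaks(), id = "s1")) |>
    add_prediction(prediction(pep_sequence(aa("A"), gap(120.5), aa("K")),
                              list(score("main", 0.9), score("extra", 1)),
                              "s1", rank = 1L, id = "p1"))
  f <- tempfile(fileext = ".xml")
  export_dnml(doc, f)
  back <- convert_dnml(f)$document
  # the subset: spectra, peaks, sequence shape, first score, links
  expect_equal(names(back$spectra), "s1")
  expect_identical(back$spectra$s1$peaks$mz, doc$spectra$s1$peaks$mz)
  expect_equal(render_sequence(back$predictions$p1$sequence),
               render_sequence(doc$predictions$p1$sequence))
  expect_equal(back$predictions$p1$scores[[1]]$value, 0.9)
  expect_length(back$predictions$p1$scores, 1)  # the lossy part
  # a second pass through DNML is the identity on the projection
  f2 <- tempfile(fileext = ".xml")
  export_dnml(back, f2)
  again <- convert_dnml(f2)$document
  expect_equal(render_sequence(again$predictions$p1$sequence),
               render_sequence(back$predictions$p1$sequence))
  expect_identical(again$spectra$s1$peaks, back$spectra$s1$peaks)
})

test_that("pepXML hits become predictions with matched modifications", {
  p <- fixture_paths(seed = 23, n = 5, modification_rate = 0.9)
  res <- convert_pepxml(p$paths$pepxml, p$paths$mgf)
  expect_equal(length(res$document$predictions),
               5 * p$fx$candidates_per_spectrum)
  expect_equal(res$report$skipped, 0L)
  expect_true("protein fields dropped" %in% res$report$lossiness)
  expect_equal(nrow(validate_document(res$document)), 0)
  # the truth contains modified peptides; mass offsets must map to PSI-MOD
  has_mod <- any(vapply(res$document$predictions, function(q) {
    any(vapply(q$sequence$elements, function(e) e$kind == "mod_aa", logical(1)))
  }, logical(1)))
  expect_true(has_mod)
  accs <- vapply(res$document$modifications, `[[`, character(1),
                 "psimod_accession")
  expect_true(all(grepl("^MOD:[0-9]{5}$", accs)))
})

test_that("pepXML oxidized methionine maps to the bundled sulfoxide entry", {
  mgf <- tempfile(fileext = ".mgf")
  write_mgf(list(spectrum(500, 2, peaks = three_peaks(), native_id = "q1")), mgf)
  f <- tempfile(fileext = ".xml")
  writeLines(paste0(
    '<msms_pipeline_analysis><msms_run_summary>',
    '<spectrum_query spectrum="q1" start_scan="1" end_scan="1" assumed_charge="2">',
    '<search_result><search_hit hit_rank="1" peptide="AMK">',
    '<modification_info><mod_aminoacid_mass position="2" mass="',
    dnmso:::fmt_num(residue_mono_mass("M") + 15.9949), '"/></modification_info>',
    '<search_score name="sc" value="1"/></search_hit></search_result>',
    '</spectrum_query></msms_run_summary></msms_pipeline_analysis>'), f)
  res <- convert_pepxml(f, mgf)
  el <- res$document$predictions[[1]]$sequence$elements[[2]]
  expect_equal(el$kind, "mod_aa")
  m <- res$document$modifications[[el$modification_ref]]
  expect_equal(m$psimod_accession, "MOD:00719")
})

test_that("unmatched pepXML mass offsets become MOD:00000 placeholders with a warning", {
  mgf <- tempfile(fileext = ".mgf")
  write_mgf(list(spectrum(500, 2, peaks = three_peaks(), native_id = "q1")), mgf)
  f <- tempfile(fileext = ".xml")
  writeLines(paste0(
    '<msms_pipeline_analysis><msms_run_summary>',
    '<spectrum_query spectrum="q1" start_scan="1" end_scan="1" assumed_charge="2">',
    '<search_result><search_hit hit_rank="1" peptide="AMK">',
    '<modification_info><mod_aminoacid_mass position="2" mass="',
    dnmso:::fmt_num(residue_mono_mass("M") + 123.456), '"/></modification_info>',
    '<search_score name="sc" value="1"/></search_hit></search_result>',
    '</spectrum_query></msms_run_summary></msms_pipeline_analysis>'), f)
  res <- convert_pepxml(f, mgf)
  el <- res$document$predictions[[1]]$sequence$elements[[2]]
  m <- res$document$modifications[[el$modification_ref]]
  expect_equal(m$psimod_accession, "MOD:00000")
  expect_match(paste(res$report$warnings, collapse = " "), "uncharacterized")
  expect_equal(nrow(validate_document(res$document)), 0)
})

test_that("a search_hit outside a spectrum_query is a structural error", {
  f <- tempfile(fileext = ".xml")
  writeLines('<msms_pipeline_analysis><search_hit peptide="AG"/></msms_pipeline_analysis>', f)
  expect_error(convert_pepxml(f, list(spectrum(1, 1, peaks = three_peaks()))),
               "structural error")
})

test_that("PEAKS-style CSV converts with ALC as the score", {
  p <- fixture_paths(seed = 29, n = 4)
  res <- convert_peaks_csv(p$paths$peaks, p$paths$mgf)
  expect_length(res$document$predictions, 4)
  expect_true(all(vapply(res$document$predictions,
                         function(q) q$scores[[1]]$name == "ALC", logical(1))))
  expect_equal(nrow(validate_document(res$document)), 0)
})

test_that("converter reports satisfy conservation on generated fixtures", {
  p <- fixture_paths(seed = 31, n = 5)
  for (nm in c("pepnovo", "lutefisk", "dnml", "pepxml", "peaks-csv")) {
    res <- convert(nm, p$paths[[switch(nm, `peaks-csv` = "peaks", nm)]],
                   spectra = if (nm == "dnml") NULL else p$paths$mgf)
    expect_equal(res$report$predictions_converted + res$report$skipped,
                 res$report$records_seen, info = nm)
    expect_equal(res$report$predictions_converted,
                 length(res$document$predictions), info = nm)
    expect_equal(dnmso::n_errors(res$document), 0, info = nm)
    # converters never invent spectra
    expect_true(length(res$document$spectra) <= 5, info = nm)
  }
})

test_that("the registry lists shipped converters and accepts new ones once", {
  lc <- list_converters()
  expect_true(all(c("pepnovo", "lutefisk", "dnml", "pepxml", "peaks-csv")
                  %in% lc$name))
  nm <- paste0("toy-tsv-", as.integer(stats::runif(1, 1, 1e9)))
  register_converter(nm, function(results, spectra, mod_table) {
    doc <- seed <- dnmso_document("toy")
    list(document = doc, report = dnmso:::new_report())
  }, description = "toy")
  expect_true(nm %in% list_converters()$name)
  expect_error(register_converter(nm, identity), "identity-conflict")
  expect_error(convert("no-such-converter", tempfile()), "unknown converter")
})

test_that("mzIdentML export has one item per prediction and all scores as params", {
  doc <- small_doc()
  xmltxt <- export_mzidentml(doc)
  x <- xml2::read_xml(xmltxt)  # well-formed
  xml2::xml_ns_strip(x)
  items <- xml2::xml_find_all(x, ".//SpectrumIdentificationItem")
  expect_length(items, length(doc$predictions))
  results <- xml2::xml_find_all(x, ".//SpectrumIdentificationResult")
  expect_length(results, 1)  # both predictions share s1 as home spectrum
  n_scores <- sum(vapply(doc$predictions, function(p) length(p$scores), integer(1)))
  params <- xml2::xml_find_all(x, ".//SpectrumIdentificationItem/userParam | .//SpectrumIdentificationItem/cvParam")
  score_params <- params[xml2::xml_attr(params, "name") %in% c("RnkScr", "PnvScr")]
  expect_length(score_params, n_scores)
  # gaps never appear in PeptideSequence, only in the userParam rendering
  seqs <- xml2::xml_text(xml2::xml_find_all(x, ".//PeptideSequence"))
  expect_true(all(grepl("^[A-Z]+$", seqs)))
  dn <- params[xml2::xml_attr(params, "name") == "de novo sequence"]
  expect_true(any(grepl("\\(100\\.00000\\)", xml2::xml_attr(dn, "value"))))
  expect_error(export_mzidentml(defect_catalogue()$defects$missing_score),
               "invalid")
})
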