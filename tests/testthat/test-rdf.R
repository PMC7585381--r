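# RDF serialization: determinism, round-trip fidelity, order preservation,
# extensibility, and a cross-check against an independent RDF parser.

test_that("an empty document serializes to document + provenance triples only", {
  doc <- dnmso_document(creator = "me", created = "2020-01-01T00:00:00Z",
                        id = "EMPTY")
  tr <- document_to_triples(doc)
  expect_setequal(unique(tr$s), "urn:dnmso:EMPTY")
  expect_true(all(grepl("rdf-syntax|dnmso", tr$p)))
  # type, localId, creator, created + 5 (empty) collection links
  expect_equal(nrow(tr), 9)
})

test_that("a 1-spectrum-1-prediction graph links sequence, score and spectrum", {
  doc <- dnmso_document("t", id = "D") |>
    add_spectrum(spectrum(500, 2, peaks = three_peaks(), id = "s1")) |>
    add_prediction(prediction(pep_sequence("AG"), score("X", 1), "s1", id = "p1"))
  tr <- document_to_triples(doc)
  pred <- "urn:dnmso:D/prediction/p1"
  expect_true(any(tr$s == pred & grepl("sequence$", tr$p)))
  expect_true(any(tr$s == pred & grepl("scores$", tr$p)))
  # the source-spectrum RDF list resolves to the spectrum node
  expect_true("urn:dnmso:D/spectrum/s1" %in%
                tr$o[grepl("rdf-syntax-ns#first$", tr$p)])
})

test_that("serialization is deterministic and refuses invalid documents", {
  doc <- small_doc()
  for (dl in c("turtle", "rdfxml", "jsonld")) {
    expect_identical(serialize_dnmso(doc, dl), serialize_dnmso(doc, dl))
  }
  bad <- defect_catalogue()$defects$orphan_prediction
  expect_error(serialize_dnmso(bad), "orphan_prediction")
})

test_that("round-trip preserves documents semantically in all dialects (seeded)", {
  for (seed in 1:8) {
    doc <- random_document(seed, 8, 15)
    for (dl in c("turtle", "rdfxml", "jsonld")) {
      back <- deserialize_dnmso(serialize_dnmso(doc, dl), dl)
      expect_true(semantic_equal(doc, back), info = paste(seed, dl))
    }
  }
})

test_that("element order and peak order survive round-trip exactly", {
  doc <- small_doc()
  for (dl in c("turtle", "rdfxml", "jsonld")) {
    back <- deserialize_dnmso(serialize_dnmso(doc, dl), dl)
    expect_identical(names(back$spectra), names(doc$spectra))
    expect_identical(names(back$predictions), names(doc$predictions))
    k2 <- vapply(back$predictions$p2$sequence$elements, `[[`, character(1), "kind")
    expect_identical(k2, c("aa", "gap", "mod_aa"))
    expect_identical(back$spectra$s1$peaks$mz, doc$spectra$s1$peaks$mz)
    sc <- vapply(back$predictions$p2$scores, `[[`, character(1), "name")
    expect_identical(sc, c("RnkScr", "PnvScr"))
  }
})

test_that("semantic_equal is reflexive and detects single-value changes", {
  doc <- small_doc()
  expect_true(semantic_equal(doc, doc))
  d2 <- doc
  d2$predictions$p1$scores[[1]]$value <- 0.90001
  expect_false(semantic_equal(doc, d2))
  d3 <- doc
  d3$spectra$s1$peaks$mz[2] <- d3$spectra$s1$peaks$mz[2] + 1e-9
  expect_false(semantic_equal(doc, d3))
})

test_that("hand-written Turtle with a missing spectrum link loads and validates", {
  ttl <- paste0(
    "@prefix dnmso: <", dnmso::DNMSO_NS, "> .\n",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .\n",
    "<urn:doc> a dnmso:Document ;\n",
    '  dnmso:localId "hand" ;\n',
    "  dnmso:predictions ( <urn:p1> ) .\n",
    "<urn:p1> a dnmso:Prediction ;\n",
    '  dnmso:localId "p1" ;\n',
    "  dnmso:scores ( <urn:p1s> ) .\n",
    '<urn:p1s> a dnmso:Score ; dnmso:scoreName "X" ; dnmso:scoreValue 0.5 .\n')
  doc <- deserialize_dnmso(ttl, "turtle")
  expect_length(doc$predictions, 1)
  v <- validate_document(doc)
  expect_true("orphan_prediction" %in% v$rule)
})

test_that("foreign-namespace triples are preserved opaquely through round-trip", {
  doc <- small_doc()
  extra <- tibble::tibble(
    s = c("urn:dnmso:SMALL", "http://example.org/x"),
    p = c("http://example.org/vocab#lab", "http://example.org/vocab#note"),
    o = c("proteomics core facility", "_:note1"),
    ot = c("literal", "iri"),
    dt = c(NA_character_, NA_character_))
  doc$extra_triples <- extra
  for (dl in c("turtle", "rdfxml", "jsonld")) {
    back <- deserialize_dnmso(serialize_dnmso(doc, dl), dl)
    expect_equal(nrow(back$extra_triples), 2, info = dl)
    expect_true(semantic_equal(doc, back), info = dl)
  }
})

test_that("unknown namespace versions raise a version error", {
  ttl <- paste0(
    "@prefix dnmso: <https://w3id.org/dnmso/9.9#> .\n",
    '<urn:doc> a dnmso:Document ; dnmso:localId "x" .\n')
  expect_error(deserialize_dnmso(ttl, "turtle"), "version error")
  expect_error(deserialize_dnmso("<urn:a> <urn:b> <urn:c> .", "turtle"),
               "version error")
})

test_that("the general Turtle parser handles ';', ',', collections and comments", {
  ttl <- paste0(
    "# a comment line\n",
    "@prefix ex: <http://example.org/> .\n",
    "ex:s ex:p ex:o1 , ex:o2 ;\n",
    '     ex:q "hi\\nthere" ;\n',
    "     ex:r ( ex:a ex:b ) .\n")
  tr <- dnmso:::general_turtle_parse(ttl)
  expect_equal(sum(tr$s == "http://example.org/s" &
                     tr$p == "http://example.org/p"), 2)
  expect_equal(tr$o[tr$p == "http://example.org/q"], "hi\nthere")
  firsts <- tr$o[grepl("#first$", tr$p)]
  expect_setequal(firsts, c("http://example.org/a", "http://example.org/b"))
  expect_error(dnmso:::general_turtle_parse("ex:s ex:p ex:o ."),
               "undefined prefix")
})

test_that("Turtle output is parseable by rdflib with the same triple count", {
  doc <- small_doc()
  f <- tempfile(fileext = ".ttl")
  write_dnmso(doc, f)
  n_ours <- nrow(document_to_triples(doc))
  py <- system2("python", c("-c", shQuote(paste0(
    "import rdflib\n",
    "g = rdflib.Graph().parse('", f, "', format='turtle')\n",
    "print(len(g))"))), stdout = TRUE, stderr = TRUE)
  expect_equal(as.integer(py[length(py)]), n_ours)
})

test_that("file extension picks the dialect on read/write", {
  doc <- small_doc()
  d <- withr::local_tempdir()
  for (ext in c("ttl", "rdf", "jsonld")) {
    f <- file.path(d, paste0("doc.", ext))
    write_dnmso(doc, f)
    expect_true(semantic_equal(doc, read_dnmso(f)))
  }
})
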