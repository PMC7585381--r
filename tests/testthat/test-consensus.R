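# Cross-tool consensus: equivalence classes of top-ranked candidates.

tool_doc <- function(seqs, title = "scan_1", mods = list(), ranks = NULL) {
  doc <- dnmso_document("tool") |>
    add_spectrum(spectrum(500, 2, peaks = three_peaks(), id = title,
                          native_id = title))
  for (m in mods) doc <- add_modification(doc, m)
  for (k in seq_along(seqs)) {
    doc <- add_prediction(doc, prediction(
      seqs[[k]], score("s", 1 - k / 10), title,
      rank = if (is.null(ranks)) k else ranks[k]))
  }
  doc
}

test_that("majority sequences form the consensus; I/L handling is optional", {
  docs <- list(tool_doc(list(pep_sequence("PEPTIDE"))),
               tool_doc(list(pep_sequence("PEPTIDE"))),
               tool_doc(list(pep_sequence("PEPTLDE"))))
  out <- consensus(docs, consensus_params(min_agreement = 2))
  expect_length(out$predictions, 1)
  p <- out$predictions[[1]]
  expect_equal(render_sequence(p$sequence), "PEPTIDE")
  ag <- vapply(p$scores, function(s) s$value, numeric(1))
  names(ag) <- vapply(p$scores, function(s) s$name, character(1))
  expect_equal(unname(ag["agreement_count"]), 2)
  expect_equal(unname(ag["mean_normalized_rank"]), 1)
  expect_equal(p$software_ref, "dnmso-consensus")
  # under I/L equivalence all three tools agree
  out2 <- consensus(docs, consensus_params(min_agreement = 2,
                                           equivalence = "IL_equivalent"))
  ag2 <- out2$predictions[[1]]$scores[[1]]$value
  expect_equal(ag2, 3)
})

test_that("min_agreement above the number of tools yields no predictions", {
  docs <- list(tool_doc(list(pep_sequence("PEPTIDE"))),
               tool_doc(list(pep_sequence("PEPTIDE"))))
  out <- consensus(docs, consensus_params(min_agreement = 3))
  expect_length(out$predictions, 0)
  expect_equal(nrow(validate_document(out)), 0)
})

test_that("gap-aware equivalence matches a gap against a residue run", {
  whole <- pep_sequence("AGPK")
  gapped <- substitute_gap(whole, 2, 3)  # G+P replaced by one gap
  expect_true(dnmso:::sequences_equivalent(whole, gapped, gap_tol = 0.01))
  off <- pep_sequence(aa("A"), gap(150), aa("K"))
  expect_false(dnmso:::sequences_equivalent(whole, off, gap_tol = 0.01))
  # strict elementwise comparisons on kinds
  expect_false(dnmso:::sequences_equivalent(pep_sequence("PEPTIDE"),
                                            pep_sequence("PEPTLDE")))
  expect_true(dnmso:::sequences_equivalent(pep_sequence("PEPTIDE"),
                                           pep_sequence("PEPTLDE"),
                                           equivalence = "IL_equivalent"))
})

test_that("consensus documents validate, serialize and round-trip", {
  docs <- list(tool_doc(list(pep_sequence("PEPTIDE"))),
               tool_doc(list(pep_sequence("PEPTIDE"))))
  out <- consensus(docs)
  expect_equal(nrow(validate_document(out)), 0)
  back <- deserialize_dnmso(serialize_dnmso(out, "turtle"), "turtle")
  expect_true(semantic_equal(out, back))
})

test_that("unmatched spectra are skipped with a warning and reported", {
  # anchor has two scans; the second tool only saw the first one (and under
  # a different precursor), so the anchor's second scan cannot be matched by
  # title, index or precursor
  d1 <- dnmso_document("t1") |>
    add_spectrum(spectrum(500, 2, peaks = three_peaks(), id = "a1",
                          native_id = "a1")) |>
    add_spectrum(spectrum(600, 2, peaks = three_peaks(), id = "a2",
                          native_id = "a2")) |>
    add_prediction(prediction(pep_sequence("PEPTIDE"), score("s", 1), "a1")) |>
    add_prediction(prediction(pep_sequence("AGAGAG"), score("s", 1), "a2"))
  d2 <- tool_doc(list(pep_sequence("PEPTIDE")), title = "b1")
  d2$spectra[[1]]$precursor_mz <- 500  # matches a1 by precursor only
  expect_warning(out <- consensus(list(d1, d2)), "not matched")
  rep <- attr(out, "report")
  expect_equal(rep$status[rep$spectrum == "a2"], "unmatched")
  expect_length(out$predictions, 1)  # a1 still reaches consensus
})

test_that("only candidates within max_rank participate", {
  agree_low <- list(
    tool_doc(list(pep_sequence("AAAA"), pep_sequence("CCCC"))),
    tool_doc(list(pep_sequence("GGGG"), pep_sequence("CCCC"))))
  top_only <- consensus(agree_low, consensus_params(min_agreement = 2))
  expect_length(top_only$predictions, 0)
  with_r2 <- consensus(agree_low, consensus_params(min_agreement = 2,
                                                   max_rank = 2))
  expect_length(with_r2$predictions, 1)
  expect_equal(render_sequence(with_r2$predictions[[1]]$sequence), "CCCC")
  # mean normalized rank over the agreeing rank-2 candidates is 1/2
  mnr <- with_r2$predictions[[1]]$scores[[2]]$value
  expect_equal(mnr, 0.5)
})

test_that("randomized consensus equals a brute-force equivalence-class oracle", {
  set.seed(77)
  alphabet <- setdiff(names(dnmso:::AA_MONO), c("I", "L"))
  for (rep in 1:10) {
    n_tools <- sample(2:4, 1)
    n_spec <- sample(2:5, 1)
    truth_seqs <- replicate(n_spec, paste(sample(alphabet, 6, TRUE), collapse = ""))
    # per spectrum and tool, emit the truth or one of two variants
    emitted <- matrix("", n_spec, n_tools)
    for (i in seq_len(n_spec)) for (t in seq_len(n_tools)) {
      emitted[i, t] <- sample(c(truth_seqs[i],
                                paste0(substr(truth_seqs[i], 1, 5), "W"),
                                paste0("W", substr(truth_seqs[i], 2, 6))),
                              1, prob = c(0.6, 0.2, 0.2))
    }
    docs <- lapply(seq_len(n_tools), function(t) {
      doc <- dnmso_document(paste0("tool", t))
      for (i in seq_len(n_spec)) {
        doc <- add_spectrum(doc, spectrum(
          100 * i, 2, peaks = three_peaks(),
          id = paste0("scan_", i), native_id = paste0("scan_", i)))
        doc <- add_prediction(doc, prediction(
          pep_sequence(emitted[i, t]), score("s", 0.9), paste0("scan_", i),
          rank = 1L))
      }
      doc
    })
    min_ag <- (2:n_tools)[sample.int(n_tools - 1L, 1)]
    out <- consensus(docs, consensus_params(min_agreement = min_ag))
    # oracle: exact string multiplicity per spectrum (no gaps, strict mode);
    # ties break toward the earliest-appearing class, as documented
    expected <- character(0)
    for (i in seq_len(n_spec)) {
      uniq <- unique(emitted[i, ])
      cnt <- vapply(uniq, function(s) sum(emitted[i, ] == s), integer(1))
      if (max(cnt) >= min_ag) expected <- c(expected, uniq[which.max(cnt)])
    }
    got <- vapply(out$predictions, function(p) render_sequence(p$sequence),
                  character(1))
    expect_equal(sort(unname(got)), sort(expected))
  }
})
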