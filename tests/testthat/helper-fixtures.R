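# Shared builders for small documents and the single-defect catalogue.

three_peaks <- function() {
  data.frame(mz = c(100.1, 200.2, 300.3), intensity = c(10, 20, 30))
}

small_doc <- function() {
  dnmso_document(creator = "test", created = "2020-01-01T00:00:00Z",
                 id = "SMALL") |>
    add_spectrum(spectrum(500.25, 2, peaks = three_peaks(), id = "s1")) |>
    add_spectrum(spectrum(600.30, 2, peaks = three_peaks(), id = "s2")) |>
    add_modification(resolve_modification("MOD:00046")) |>
    add_software(software("toolX", "1.0")) |>
    add_prediction(prediction(pep_sequence("PEPTIDE"),
                              score("RnkScr", 0.9), "s1",
                              software_ref = "toolX", rank = 1L, id = "p1")) |>
    add_prediction(prediction(pep_sequence(aa("G"), gap(100),
                                           mod_aa("S", "MOD:00046")),
                              list(score("RnkScr", 0.5), score("PnvScr", 12)),
                              c("s1", "s2"), rank = 2L, id = "p2"))
}

# One clean document plus a catalogue of single-defect variants, each named
# by the validation rule it must trigger. Defects are injected by direct
# structural surgery (the construction guards would reject them).
defect_catalogue <- function() {
  clean <- small_doc()
  defects <- list()

  d <- clean
  d$predictions$p1$source_spectrum_refs <- character(0)
  defects$orphan_prediction <- d

  d <- clean
  d$predictions$p1$scores <- list()
  defects$missing_score <- d

  d <- clean
  d$predictions$p1$source_spectrum_refs <- "s99"
  defects$dangling_spectrum_ref <- d

  d <- clean
  d$modifications[["MOD:00046"]]$psimod_accession <- "phospho"
  defects$missing_psimod <- d

  d <- clean
  d$spectra$s1$peaks <- data.frame(mz = c(300, 100, 200),
                                   intensity = c(1, 2, 3))
  defects$unsorted_peaks <- d

  d <- clean
  d$spectra <- c(d$spectra, stats::setNames(d$spectra["s1"], "s1"))
  defects$duplicate_id <- d

  d <- clean
  d$predictions$p2$sequence$elements[[3]]$modification_ref <- "MOD:99999"
  defects$dangling_modification_ref <- d

  d <- clean
  d$spectra$s1$peaks <- empty_peaks_df()
  defects$spectrum_no_data <- d

  list(clean = clean, defects = defects)
}

empty_peaks_df <- function() data.frame(mz = numeric(0), intensity = numeric(0))

random_spectrum <- function(n_peaks = 20) {
  spectrum(precursor_mz = stats::runif(1, 300, 1500),
           precursor_charge = sample(1:3, 1),
           peaks = data.frame(mz = sort(stats::runif(n_peaks, 100, 2000)),
                              intensity = 10^stats::runif(n_peaks, 0, 6)))
}

# Monoisotopic masses from elemental composition: the independent oracle for
# the residue mass table (atomic masses from the standard isotope tables).
ATOM <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
          O = 15.9949146196, S = 31.97207100)
compo_mass <- function(compo) sum(ATOM[rep(names(compo), compo)])
RESIDUE_COMPOSITIONS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))
oracle_residue_mass <- function(res) compo_mass(RESIDUE_COMPOSITIONS[[res]])
ORACLE_WATER <- compo_mass(c(H = 2, O = 1))

# Random sequence over the full element vocabulary, for render/parse and
# serialization property tests.
random_sequence <- function(mod_ids = character(0)) {
  len <- sample(2:8, 1)
  els <- lapply(seq_len(len), function(k) {
    r <- stats::runif(1)
    if (r < 0.15) {
      gap(round(stats::runif(1, 50, 400), 5))
    } else if (r < 0.3 && length(mod_ids) > 0) {
      mod_aa(sample(names(dnmso:::AA_MONO), 1), sample(mod_ids, 1))
    } else {
      aa(sample(names(dnmso:::AA_MONO), 1))
    }
  })
  do.call(pep_sequence, els)
}

run_cli <- function(args, input = NULL) {
  cli <- system.file("cli", "dnmso.R", package = "dnmso")
  res <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), shQuote(c(cli, args)),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(res, "status") %||% 0L, output = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
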