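# Deterministic synthetic-data generator: random tryptic-length peptides,
# theoretical b/y fragment spectra with uniform noise peaks, and legacy tool
# result files in every shipped dialect, with a controllable fraction of
# spectra on which the simulated tools agree. Everything derives from one
# integer seed, so fixtures are generated at test time rather than stored.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-data generation parameters
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param n_spectra Number of ground-truth peptide/spectrum pairs.
#' @param n_tools Number of simulated de novo tools.
#' @param peptide_length_range Min/max peptide length (residues).
#' @param modification_rate Probability that a peptide carries one PTM drawn
#'   from the bundled PSI-MOD subset (residue-compatible).
#' @param gap_rate Probability that a lower-ranked candidate replaces a
#'   terminal residue run by a mass gap.
#' @param agreement_profile Fraction of spectra on which all tools emit the
#'   true sequence as their top candidate; on the rest each tool emits a
#'   distinct single-substitution variant.
#' @param candidates_per_spectrum Ranked candidates per spectrum per tool.
#' @return A `dnmso_fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_spectra = 20L, n_tools = 3L,
                         peptide_length_range = c(7L, 12L),
                         modification_rate = 0.2, gap_rate = 0.2,
                         agreement_profile = 1.0,
                         candidates_per_spectrum = 3L) {
  stopifnot(n_spectra >= 1, n_tools >= 1,
            modification_rate >= 0, modification_rate <= 1,
            gap_rate >= 0, gap_rate <= 1,
            agreement_profile >= 0, agreement_profile <= 1)
  structure(list(seed = as.integer(seed), n_spectra = as.integer(n_spectra),
                 n_tools = as.integer(n_tools),
                 peptide_length_range = as.integer(peptide_length_range),
                 modification_rate = modification_rate, gap_rate = gap_rate,
                 agreement_profile = agreement_profile,
                 candidates_per_spectrum = as.integer(candidates_per_spectrum)),
            class = "dnmso_fixture_spec")
}

element_masses <- function(seq, mods) {
  vapply(seq$elements, function(el) {
    switch(el$kind,
           aa = residue_mono_mass(el$residue),
           gap = el$mass,
           mod_aa = residue_mono_mass(el$residue) + mods[[el$modification_ref]]$mono_mass_delta)
  }, numeric(1))
}

#' Theoretical singly-protonated b/y fragment m/z values
#'
#' b ions are prefix masses plus a proton; y ions are suffix masses plus
#' water and a proton.
#'
#' @param seq A [pep_sequence()].
#' @param modifications Modification table resolving any modified residues.
#' @return A tibble with columns `ion` (`b1`, `y1`, ...) and `mz`.
#' @export
fragment_ions <- function(seq, modifications = list()) {
  m <- element_masses(seq, modifications)
  n <- length(m)
  if (n < 2) return(tibble::tibble(ion = character(0), mz = numeric(0)))
  b <- cumsum(m)[-n] + MASS_PROTON
  y <- rev(cumsum(rev(m))[-n]) + MASS_WATER + MASS_PROTON
  tibble::tibble(
    ion = c(paste0("b", seq_len(n - 1)), paste0("y", rev(seq_len(n - 1)))),
    mz = c(b, y))
}

#' Generate ground-truth peptides and their synthetic spectra
#'
#' Random peptides from the 20-letter alphabet (optionally carrying one
#' residue-compatible modification from the bundled subset), fragmented into
#' singly-protonated b/y ions plus an equal number of uniform-random noise
#' peaks with log-uniform intensities; the precursor is the doubly
#' protonated peptide, so the precursor neutral mass equals
#' [sequence_mono_mass()] exactly. Deterministic for a fixed seed.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `records` (each `list(id, sequence, spectrum)`) and
#'   `modifications` (named list of the [modification()]s used).
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "dnmso_fixture_spec"))
  psimod <- load_psimod()
  with_seed(spec$seed, {
    mods_used <- list()
    records <- vector("list", spec$n_spectra)
    for (i in seq_len(spec$n_spectra)) {
      len <- sample(spec$peptide_length_range[1]:spec$peptide_length_range[2], 1)
      letters <- sample(names(AA_MONO), len, replace = TRUE)
      els <- lapply(letters, aa)
      if (stats::runif(1) < spec$modification_rate) {
        # pick a residue-specific modification compatible with the peptide
        cand <- psimod[psimod$residues != "any" & psimod$terminus == "none", ]
        hit <- which(vapply(seq_len(nrow(cand)), function(r) {
          any(strsplit(cand$residues[r], "")[[1]] %in% letters)
        }, logical(1)))
        if (length(hit) > 0) {
          row <- cand[hit[sample.int(length(hit), 1)], ]
          m <- row_to_modification(row)
          pos <- which(letters %in% strsplit(row$residues, "")[[1]])
          pos <- pos[sample.int(length(pos), 1)]
          els[[pos]] <- mod_aa(letters[pos], m$local_id)
          mods_used[[m$local_id]] <- m
        }
      }
      pep <- do.call(pep_sequence, els)
      neutral <- sequence_mono_mass(pep, mods_used)
      frags <- fragment_ions(pep, mods_used)
      n_noise <- nrow(frags)
      noise_mz <- stats::runif(n_noise, min = 100, max = max(frags$mz) * 1.1)
      pk <- tibble::tibble(
        mz = c(frags$mz, noise_mz),
        intensity = c(10^stats::runif(nrow(frags), 3, 5),
                      10^stats::runif(n_noise, 1, 3)))
      title <- sprintf("synthetic_scan_%03d", i)
      records[[i]] <- list(
        id = title,
        sequence = pep,
        spectrum = spectrum(
          precursor_mz = (neutral + 2 * MASS_PROTON) / 2,
          precursor_charge = 2L, peaks = pk, id = title, native_id = title,
          retention_time_s = 60 * i, fragmentation = "CID",
          normalize = TRUE))
    }
    list(records = records, modifications = mods_used)
  })
}

#' Replace a residue run by a mass gap of exactly its summed mass
#'
#' @param seq A [pep_sequence()].
#' @param from,to Element positions (inclusive) of the run to replace.
#' @param modifications Modification table for modified residues in the run.
#' @return A new sequence of identical neutral mass.
#' @export
substitute_gap <- function(seq, from, to, modifications = list()) {
  stopifnot(from >= 1, to <= seq_length(seq), from <= to)
  m <- element_masses(seq, modifications)
  els <- c(seq$elements[seq_len(from - 1)],
           list(gap(sum(m[from:to]))),
           if (to < seq_length(seq)) seq$elements[(to + 1):seq_length(seq)])
  do.call(pep_sequence, els)
}

# deterministic single-substitution variant, distinct per tool, avoiding
# I/L swaps so that strict and I/L-equivalent modes genuinely differ
substitute_residue <- function(pep, tool) {
  plain <- which(vapply(pep$elements, function(e) e$kind == "aa", logical(1)))
  pos <- plain[1 + (tool - 1) %% length(plain)]
  old <- pep$elements[[pos]]$residue
  alphabet <- setdiff(names(AA_MONO), c(old, if (old %in% c("I", "L")) c("I", "L")))
  els <- pep$elements
  els[[pos]] <- aa(alphabet[1 + (tool - 1) %% length(alphabet)])
  do.call(pep_sequence, els)
}

render_for_tool <- function(pep, mods, style = c("delta", "plain", "annotated"),
                            gap_open = "[", gap_close = "]") {
  style <- match.arg(style)
  paste(vapply(pep$elements, function(el) {
    switch(el$kind,
           aa = el$residue,
           gap = paste0(gap_open, sprintf("%.5f", el$mass), gap_close),
           mod_aa = {
             m <- mods[[el$modification_ref]]
             switch(style,
                    delta = sprintf("%s%+.6f", el$residue, m$mono_mass_delta),
                    plain = el$residue,
                    annotated = paste0(el$residue, "[", m$psimod_accession, "]"))
           })
  }, character(1)), collapse = "")
}

#' Write simulated tool outputs for a ground truth
#'
#' Emits the spectra as MGF (plus mzML/mzXML copies) and one result file per
#' shipped dialect: `pepnovo.txt`, `lutefisk.txt`, `dnml.xml`, `pepxml.xml`,
#' `peaks.csv`. The first `n_tools` dialects act as the simulated tools: on
#' an `agreement_profile` fraction of spectra every tool's top candidate is
#' the true sequence; on the rest each tool emits a distinct
#' single-substitution variant. Lower-ranked candidates are further
#' perturbed (substitutions, and terminal gap replacements where the dialect
#' can express them). Scores decrease with rank and are drawn
#' deterministically from the seed.
#'
#' @param truth Result of [generate_ground_truth()].
#' @param spec The same [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, with attribute `agree`: the logical
#'   per-spectrum agreement draws.
#' @export
write_tool_outputs <- function(truth, spec, dir) {
  stopifnot(inherits(spec, "dnmso_fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- truth$records
  mods <- truth$modifications
  paths <- list(
    mgf = file.path(dir, "spectra.mgf"),
    mzml = file.path(dir, "spectra.mzML"),
    mzxml = file.path(dir, "spectra.mzXML"),
    pepnovo = file.path(dir, "pepnovo.txt"),
    lutefisk = file.path(dir, "lutefisk.txt"),
    dnml = file.path(dir, "dnml.xml"),
    pepxml = file.path(dir, "pepxml.xml"),
    peaks = file.path(dir, "peaks.csv"))
  spectra <- lapply(records, `[[`, "spectrum")
  write_mgf(spectra, paths$mgf)
  write_mzml(spectra, paths$mzml)
  write_mzxml(spectra, paths$mzxml)

  with_seed(spec$seed + 1L, {
    agree <- stats::runif(length(records)) < spec$agreement_profile
    # candidate sequences per spectrum x tool x rank
    n_rank <- spec$candidates_per_spectrum
    cands <- lapply(seq_along(records), function(i) {
      pep <- records[[i]]$sequence
      lapply(seq_len(5), function(tool) {  # one "tool" per dialect
        top <- if (agree[i]) pep else substitute_residue(pep, tool)
        lower <- lapply(seq_len(max(0L, n_rank - 1L)), function(r) {
          v <- substitute_residue(pep, tool + r * 5L)
          can_gap <- tool <= 3  # pepnovo/lutefisk/dnml dialects express gaps
          if (can_gap && stats::runif(1) < spec$gap_rate) {
            run <- min(2L, seq_length(v) - 1L)
            v <- substitute_gap(v, 1L, run, mods)
          }
          v
        })
        c(list(top), lower)
      })
    })
    base_scores <- matrix(stats::runif(length(records) * 5, 0.7, 0.99),
                          nrow = length(records))

    # -- PepNovo (tool 1): >> header + fixed tab layout
    pn <- character(0)
    for (i in seq_along(records)) {
      rec <- records[[i]]
      pn <- c(pn, sprintf(">> %d %s", i - 1L, rec$id),
              paste(PEPNOVO_HEADER, collapse = "\t"))
      for (rk in seq_len(n_rank)) {
        pep <- cands[[i]][[1]][[rk]]
        ngap <- 0; cgap <- 0
        els <- pep$elements
        if (els[[1]]$kind == "gap") { ngap <- els[[1]]$mass; els <- els[-1] }
        if (els[[length(els)]]$kind == "gap") {
          cgap <- els[[length(els)]]$mass; els <- els[-length(els)]
        }
        body <- do.call(pep_sequence, els)
        mh <- sequence_mono_mass(pep, mods) + MASS_PROTON
        pn <- c(pn, paste(c(
          rk - 1L, sprintf("%.3f", base_scores[i, 1] - 0.2 * (rk - 1)),
          sprintf("%.1f", 100 * (base_scores[i, 1] - 0.2 * (rk - 1))),
          sprintf("%.3f", ngap), sprintf("%.3f", cgap),
          sprintf("%.4f", mh), "2",
          render_for_tool(body, mods, "delta")), collapse = "\t"))
      }
      pn <- c(pn, "")
    }
    writeLines(pn, paths$pepnovo)

    # -- Lutefisk (tool 2): Spectrum: sections, two score columns
    lf <- c("# Lutefisk de novo results (synthetic)")
    for (i in seq_along(records)) {
      lf <- c(lf, paste0("Spectrum: ", records[[i]]$id),
              paste(LUTEFISK_HEADER, collapse = "\t"))
      for (rk in seq_len(n_rank)) {
        pep <- cands[[i]][[2]][[rk]]
        lf <- c(lf, paste(c(
          rk, sprintf("%.3f", base_scores[i, 2] - 0.2 * (rk - 1)),
          sprintf("%.3f", base_scores[i, 2] - 0.25 * (rk - 1)),
          render_for_tool(pep, mods, "delta")), collapse = "\t"))
      }
    }
    writeLines(lf, paths$lutefisk)

    # -- DNML (tool 3): XML with annotated sequences + modification table
    mod_xml <- paste(vapply(mods, function(m) sprintf(
      '<modification accession="%s" name="%s" monoDelta="%s" avgDelta="%s" residues="%s"/>',
      m$psimod_accession, xml_escape(m$name), fmt_num(m$mono_mass_delta),
      fmt_num(m$avg_mass_delta), paste(m$residue_specificity, collapse = "")),
      character(1)), collapse = "")
    spec_xml <- vapply(seq_along(records), function(i) {
      s <- records[[i]]$spectrum
      sprintf('<spectrum id="%s" precursorMz="%s" charge="%d"><peaks>%s</peaks></spectrum>',
              s$id, fmt_num(s$precursor_mz), s$precursor_charge,
              paste(paste0(fmt_num(s$peaks$mz), ":", fmt_num(s$peaks$intensity)),
                    collapse = " "))
    }, character(1))
    pred_xml <- character(0)
    for (i in seq_along(records)) {
      for (rk in seq_len(n_rank)) {
        pep <- cands[[i]][[3]][[rk]]
        pred_xml <- c(pred_xml, sprintf(
          '<prediction id="p%d_%d" spectrumRefs="%s" rank="%d" score="%.3f"><sequence>%s</sequence></prediction>',
          i, rk, records[[i]]$id, rk, base_scores[i, 3] - 0.2 * (rk - 1),
          render_for_tool(pep, mods, "annotated", gap_open = "(", gap_close = ")")))
      }
    }
    writeLines(sprintf(
      '<?xml version="1.0" encoding="utf-8"?>\n<dnml version="1.0"><modifications>%s</modifications><spectra>%s</spectra><predictions>%s</predictions></dnml>',
      mod_xml, paste(spec_xml, collapse = ""), paste(pred_xml, collapse = "")),
      paths$dnml, sep = "\n")

    # -- pepXML (tool 4): substitution-only variants (no gap syntax)
    queries <- vapply(seq_along(records), function(i) {
      rec <- records[[i]]
      neutral <- precursor_neutral_mass(rec$spectrum$precursor_mz, 2)
      hits <- vapply(seq_len(n_rank), function(rk) {
        pep <- cands[[i]][[4]][[rk]]
        letters <- vapply(pep$elements, function(e) e$residue %||% "X", character(1))
        mod_info <- ""
        midx <- which(vapply(pep$elements, function(e) e$kind == "mod_aa", logical(1)))
        if (length(midx) > 0) {
          mams <- vapply(midx, function(k) {
            el <- pep$elements[[k]]
            sprintf('<mod_aminoacid_mass position="%d" mass="%s"/>', k,
                    fmt_num(residue_mono_mass(el$residue) +
                            mods[[el$modification_ref]]$mono_mass_delta))
          }, character(1))
          mod_info <- paste0('<modification_info>', paste(mams, collapse = ""),
                             '</modification_info>')
        }
        sprintf('<search_hit hit_rank="%d" peptide="%s" protein="unmapped">%s<search_score name="denovo_score" value="%.3f"/><search_score name="complementarity" value="%.3f"/></search_hit>',
                rk, paste(letters, collapse = ""), mod_info,
                base_scores[i, 4] - 0.2 * (rk - 1),
                base_scores[i, 4] - 0.1 * (rk - 1))
      }, character(1))
      sprintf('<spectrum_query spectrum="%s" start_scan="%d" end_scan="%d" precursor_neutral_mass="%s" assumed_charge="2"><search_result>%s</search_result></spectrum_query>',
              rec$id, i, i, fmt_num(neutral), paste(hits, collapse = ""))
    }, character(1))
    writeLines(sprintf(
      '<?xml version="1.0" encoding="utf-8"?>\n<msms_pipeline_analysis xmlns="http://regis-web.systemsbiology.net/pepXML"><msms_run_summary>%s</msms_run_summary></msms_pipeline_analysis>',
      paste(queries, collapse = "")), paths$pepxml, sep = "\n")

    # -- PEAKS-style CSV (tool 5): top candidate only
    rows <- vapply(seq_along(records), function(i) {
      pep <- cands[[i]][[5]][[1]]
      sprintf('%s,%s,%.1f,%s,2', records[[i]]$id,
              render_for_tool(pep, mods, "delta"),
              100 * base_scores[i, 5], fmt_num(records[[i]]$spectrum$precursor_mz))
    }, character(1))
    writeLines(c(paste(PEAKS_HEADER, collapse = ","), rows), paths$peaks)

    structure(paths, agree = agree)
  })
}

#' Random documents for round-trip and oracle testing
#'
#' Builds a structurally rich, valid document with random spectra (inline
#' and external-reference), modifications, software, multi-score and
#' multi-spectrum predictions, per-element confidences and supporting peaks.
#'
#' @param seed Integer seed.
#' @param max_spectra,max_predictions Upper bounds on the collection sizes
#'   (actual sizes are drawn uniformly).
#' @return A valid `dnmso_document`.
#' @export
random_document <- function(seed, max_spectra = 10L, max_predictions = 20L) {
  with_seed(seed, {
    doc <- dnmso_document(creator = "random_document",
                          created = "2020-01-01T00:00:00Z",
                          id = sprintf("RAND_%d", seed))
    doc <- add_cv_source(doc, cv_source("PSI-MOD", "PSI-MOD ontology", "1.2"))
    doc <- add_cv_source(doc, cv_source("PSI-MS", "PSI-MS controlled vocabulary", "4.1"))
    psimod <- load_psimod()
    n_mod <- sample(0:3, 1)
    for (k in sample(seq_len(nrow(psimod)), n_mod)) {
      m <- row_to_modification(psimod[k, ])
      if (is.null(doc$modifications[[m$local_id]])) doc <- add_modification(doc, m)
    }
    doc <- add_software(doc, software("toolA", "1.0"))
    doc <- add_software(doc, software(
      "toolB", "2.1", parameters = list(
        cv_param("PSI-MS", "MS:1000041", "charge state", "2"),
        threshold = "0.5")))
    ns <- sample(seq_len(max_spectra), 1)
    for (k in seq_len(ns)) {
      n_pk <- sample(0:30, 1)
      ext <- NULL
      if (n_pk == 0 || stats::runif(1) < 0.15) {
        ext <- external_ref("run1.mzML", "mzML", native_id = sprintf("scan=%d", k))
      }
      pk <- if (n_pk > 0) {
        tibble::tibble(mz = sort(stats::runif(n_pk, 100, 2000)),
                       intensity = 10^stats::runif(n_pk, 1, 5))
      } else NULL
      doc <- add_spectrum(doc, spectrum(
        precursor_mz = stats::runif(1, 300, 1500),
        precursor_charge = sample(c(NA_integer_, 1:3), 1),
        peaks = pk, external_ref = ext,
        retention_time_s = if (stats::runif(1) < 0.5) stats::runif(1, 0, 3600) else NULL,
        fragmentation = sample(c(NA, "CID", "ETD", "HCD"), 1) |>
          (\(x) if (is.na(x)) NULL else x)()))
    }
    spec_ids <- names(doc$spectra)
    inline_ids <- spec_ids[vapply(doc$spectra, has_inline_peaks, logical(1))]
    np <- sample(seq_len(max_predictions), 1)
    for (k in seq_len(np)) {
      len <- sample(3:10, 1)
      els <- lapply(sample(names(AA_MONO), len, replace = TRUE), function(res) {
        if (length(doc$modifications) > 0 && stats::runif(1) < 0.1) {
          mod_aa(res, sample(names(doc$modifications), 1),
                 confidence = round(stats::runif(1), 3))
        } else if (stats::runif(1) < 0.1) {
          gap(round(stats::runif(1, 50, 300), 5))
        } else {
          aa(res, confidence = if (stats::runif(1) < 0.3) round(stats::runif(1), 3) else NULL)
        }
      })
      if (length(inline_ids) > 0 && stats::runif(1) < 0.2) {
        sid <- sample(inline_ids, 1)
        s <- doc$spectra[[sid]]
        els[[1]]$supporting_peaks <- tibble::tibble(
          spectrum_id = sid, peak_index = sample(seq_len(nrow(s$peaks)), 1))
      }
      n_src <- sample(1:min(3, length(spec_ids)), 1)
      n_sc <- sample(1:3, 1)
      doc <- add_prediction(doc, prediction(
        sequence = do.call(pep_sequence, els),
        scores = lapply(seq_len(n_sc), function(j) {
          score(c("RnkScr", "PnvScr", "ALC")[j], round(stats::runif(1), 6),
                cv_accession = if (j == 1 && stats::runif(1) < 0.3) "MS:1001143" else NULL)
        }),
        source_spectrum_refs = sample(spec_ids, n_src),
        software_ref = sample(c("toolA", "toolB"), 1),
        rank = sample(c(NA, 1:3), 1) |> (\(x) if (is.na(x)) NULL else x)()))
    }
    doc
  })
}
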