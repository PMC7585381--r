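# Converters from legacy de novo result formats into documents, plus the
# lossy mzIdentML exporter. The exact column layouts of the flat-text tools
# vary by version; the dialects shipped here are frozen by the exemplar
# fixtures in inst/extdata/ and the parsers fail loudly with a dialect hint
# on anything else. Converters never emit orphan predictions: a record whose
# spectrum cannot be matched is skipped with a warning in the report.

new_report <- function() {
  structure(list(spectra_read = 0L, records_seen = 0L,
                 predictions_converted = 0L, skipped = 0L,
                 warnings = character(0), lossiness = character(0)),
            class = "dnmso_report")
}

#' @export
print.dnmso_report <- function(x, ...) {
  cat(sprintf("<conversion report> %d spectra read; %d records: %d converted, %d skipped\n",
              x$spectra_read, x$records_seen, x$predictions_converted, x$skipped))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  for (l in x$lossiness) cat("  lossy: ", l, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.dnmso_report <- function(x, ...) {
  tibble::tibble(spectra_read = x$spectra_read, records_seen = x$records_seen,
                 predictions_converted = x$predictions_converted,
                 skipped = x$skipped, n_warnings = length(x$warnings))
}

as_spectra_list <- function(spectra) {
  if (is.null(spectra)) return(list())
  if (is.character(spectra)) return(read_spectra(spectra))
  if (inherits(spectra, "dnmso_spectrum")) return(list(spectra))
  if (is.list(spectra)) return(spectra)
  stop("spectra must be a file path or a list of spectrum objects", call. = FALSE)
}

# Seed an output document with the companion spectra (all of them; orphans
# are permitted and downstream consensus benefits from having every scan).
seed_document <- function(spectra, creator) {
  doc <- dnmso_document(creator = creator)
  for (s in spectra) {
    if (is.null(s$id)) s$id <- s$native_id
    doc <- add_spectrum(doc, s)
  }
  doc
}

# First-match-wins spectrum lookup: exact title/native id, then scan index,
# then precursor m/z within 0.01 Th.
find_spectrum_id <- function(doc, title = NULL, index = NULL, mz = NULL) {
  ids <- names(doc$spectra)
  if (!is.null(title)) {
    for (k in seq_along(ids)) {
      s <- doc$spectra[[k]]
      if (identical(s$native_id %||% s$id, title) || identical(s$id, title)) {
        return(ids[k])
      }
    }
  }
  if (!is.null(index) && !is.na(index) && index >= 1 && index <= length(ids)) {
    return(ids[index])
  }
  if (!is.null(mz) && !is.na(mz)) {
    for (k in seq_along(ids)) {
      smz <- doc$spectra[[k]]$precursor_mz
      if (!is.na(smz) && abs(smz - mz) <= 0.01) return(ids[k])
    }
  }
  NULL
}

# Resolve a residue + observed mass delta against the modification table;
# registers the match (or the MOD:00000 placeholder) in the document.
resolve_delta_mod <- function(doc, report, residue, delta, mod_table, tol = 0.01) {
  m <- match_modification_by_delta(delta, residue = residue, table = mod_table,
                                   tol = tol)
  if (is.null(m)) {
    report$warnings <- c(report$warnings, sprintf(
      "uncharacterized modification %+0.4f Da on %s mapped to placeholder MOD:00000 (user mapping required)",
      delta, residue))
    local_id <- sprintf("MOD:00000@%+0.4f", delta)
    m <- modification("MOD:00000", "uncharacterized protein modification",
                      mono_mass_delta = delta, residue_specificity = residue,
                      local_id = local_id)
  }
  if (is.null(doc$modifications[[m$local_id]])) doc <- add_modification(doc, m)
  list(doc = doc, report = report, ref = m$local_id)
}

# Parse a flat-dialect peptide string: residues, optional +/-delta suffix per
# residue (PepNovo/PEAKS style), optional [mass] / (mass) gaps.
parse_tool_sequence <- function(doc, report, text, mod_table,
                                gap_open = "[", gap_close = "]") {
  els <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == gap_open) {
      close <- regexpr(gap_close, substr(text, i + 1L, n), fixed = TRUE)
      if (close < 0) stop("dialect error: unbalanced gap bracket in '", text, "'",
                          call. = FALSE)
      mass <- as.numeric(substr(text, i + 1L, i + close - 1L))
      els[[length(els) + 1L]] <- gap(mass)
      i <- i + close + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      rest <- substr(text, i + 1L, n)
      m <- regmatches(rest, regexpr("^\\(?([+-][0-9]+\\.?[0-9]*)\\)?", rest))
      if (length(m) == 1 && nzchar(m)) {
        delta <- as.numeric(gsub("[()]", "", m))
        res <- resolve_delta_mod(doc, report, ch, delta, mod_table)
        doc <- res$doc; report <- res$report
        els[[length(els) + 1L]] <- mod_aa(ch, res$ref)
        i <- i + 1L + nchar(m)
      } else {
        els[[length(els) + 1L]] <- aa(ch)
        i <- i + 1L
      }
    } else {
      stop("dialect error: unexpected character '", ch, "' in sequence '",
           text, "'", call. = FALSE)
    }
  }
  list(doc = doc, report = report, seq = do.call(pep_sequence, els))
}

# ---- PepNovo --------------------------------------------------------------

PEPNOVO_HEADER <- c("#Index", "RnkScr", "PnvScr", "N-Gap", "C-Gap", "[M+H]",
                    "Charge", "Sequence")

#' Convert PepNovo-style results
#'
#' Parses the frozen PepNovo flat-text dialect: per queried spectrum a
#' `">> <index> <title>"` header, a tab-separated column header
#' (`#Index RnkScr PnvScr N-Gap C-Gap [M+H] Charge Sequence`) and one row
#' per ranked candidate. Positive N-/C-gap masses become leading/trailing
#' gap elements; both score columns are kept as named scores; rank is the
#' candidate index + 1. Candidates are linked to the companion spectra by
#' title, then scan index, then precursor m/z.
#'
#' @param results Path to the results file.
#' @param spectra Companion spectra: a peak-list file path (MGF/mzML/mzXML)
#'   or a list of [spectrum()] objects. Required — the format mandates
#'   source spectra.
#' @param mod_table Modification table ([load_psimod()]) used to map residue
#'   mass offsets (0.01 Da tolerance); unmatched offsets become a
#'   `MOD:00000` placeholder with a warning.
#' @return A list with elements `document` and `report`.
#' @export
convert_pepnovo <- function(results, spectra, mod_table = load_psimod()) {
  sp <- as_spectra_list(spectra)
  if (length(sp) == 0) {
    stop("unresolved-spectrum error: PepNovo conversion requires companion spectra",
         call. = FALSE)
  }
  doc <- seed_document(sp, creator = "dnmso pepnovo converter")
  doc <- add_software(doc, software("PepNovo", version = "dialect-frozen"))
  report <- new_report()
  report$spectra_read <- length(sp)
  lines <- readLines(results, warn = FALSE)
  cur_title <- NULL
  cur_index <- NA_integer_
  header_seen <- FALSE
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, ">>")) {
      m <- regmatches(line, regexec("^>>\\s+(\\S+)\\s+(.*)$", line))[[1]]
      if (length(m) == 0) stop("dialect error: bad PepNovo block header '", line,
                               "'", call. = FALSE)
      cur_index <- as.integer(m[2]) + 1L
      cur_title <- m[3]
      header_seen <- FALSE
      next
    }
    if (startsWith(line, "#")) {
      cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (!identical(cols, PEPNOVO_HEADER)) {
        stop("dialect error: unknown PepNovo column layout; expected '",
             paste(PEPNOVO_HEADER, collapse = " "), "'", call. = FALSE)
      }
      header_seen <- TRUE
      next
    }
    report$records_seen <- report$records_seen + 1L
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (!header_seen || length(fields) != length(PEPNOVO_HEADER)) {
      report$skipped <- report$skipped + 1L
      report$warnings <- c(report$warnings,
                           paste0("malformed PepNovo row skipped: '", line, "'"))
      next
    }
    sid <- find_spectrum_id(doc, title = cur_title, index = cur_index,
                            mz = suppressWarnings(as.numeric(fields[6])))
    if (is.null(sid)) {
      stop("unresolved-spectrum error: PepNovo block '", cur_title,
           "' has no matching spectrum in the companion file", call. = FALSE)
    }
    parsed <- tryCatch(
      parse_tool_sequence(doc, report, fields[8], mod_table),
      error = function(e) e)
    if (inherits(parsed, "error")) {
      report$skipped <- report$skipped + 1L
      report$warnings <- c(report$warnings, conditionMessage(parsed))
      next
    }
    doc <- parsed$doc; report <- parsed$report
    els <- parsed$seq$elements
    ngap <- as.numeric(fields[4]); cgap <- as.numeric(fields[5])
    if (!is.na(ngap) && ngap > 0) els <- c(list(gap(ngap)), els)
    if (!is.na(cgap) && cgap > 0) els <- c(els, list(gap(cgap)))
    doc <- add_prediction(doc, prediction(
      sequence = do.call(pep_sequence, els),
      scores = list(score("RnkScr", as.numeric(fields[2])),
                    score("PnvScr", as.numeric(fields[3]))),
      source_spectrum_refs = sid, software_ref = "PepNovo",
      rank = as.integer(fields[1]) + 1L))
    report$predictions_converted <- report$predictions_converted + 1L
  }
  list(document = doc, report = report)
}

# ---- Lutefisk -------------------------------------------------------------

LUTEFISK_HEADER <- c("Rank", "Pr(c)", "Quality", "Sequence")

#' Convert Lutefisk-style results
#'
#' Frozen dialect: per-spectrum sections introduced by `"Spectrum: <title>"`,
#' a tab-separated header `Rank Pr(c) Quality Sequence` and candidate rows
#' whose sequences carry bracketed gap masses (`[100.000]AGK`). Both score
#' columns become distinct named scores on each prediction.
#'
#' @inheritParams convert_pepnovo
#' @return A list with elements `document` and `report`.
#' @export
convert_lutefisk <- function(results, spectra, mod_table = load_psimod()) {
  sp <- as_spectra_list(spectra)
  doc <- seed_document(sp, creator = "dnmso lutefisk converter")
  doc <- add_software(doc, software("Lutefisk", version = "dialect-frozen"))
  report <- new_report()
  report$spectra_read <- length(sp)
  lines <- readLines(results, warn = FALSE)
  cur_title <- NULL
  cur_index <- 0L
  header_seen <- FALSE
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "Spectrum:")) {
      cur_title <- trimws(sub("^Spectrum:", "", line))
      cur_index <- cur_index + 1L
      header_seen <- FALSE
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (identical(fields, LUTEFISK_HEADER)) { header_seen <- TRUE; next }
    report$records_seen <- report$records_seen + 1L
    if (!header_seen || length(fields) != length(LUTEFISK_HEADER)) {
      report$skipped <- report$skipped + 1L
      report$warnings <- c(report$warnings,
                           paste0("malformed Lutefisk row skipped: '", line, "'"))
      next
    }
    sid <- find_spectrum_id(doc, title = cur_title, index = cur_index)
    if (is.null(sid)) {
      report$skipped <- report$skipped + 1L
      report$warnings <- c(report$warnings, paste0(
        "Lutefisk section '", cur_title, "' has no matching spectrum; row skipped"))
      next
    }
    parsed <- tryCatch(parse_tool_sequence(doc, report, fields[4], mod_table),
                       error = function(e) e)
    if (inherits(parsed, "error")) {
      report$skipped <- report$skipped + 1L
      report$warnings <- c(report$warnings, conditionMessage(parsed))
      next
    }
    doc <- parsed$doc; report <- parsed$report
    doc <- add_prediction(doc, prediction(
      sequence = parsed$seq,
      scores = list(score("Pr(c)", as.numeric(fields[2])),
                    score("Quality", as.numeric(fields[3]))),
      source_spectrum_refs = sid, software_ref = "Lutefisk",
      rank = as.integer(fields[1])))
    report$predictions_converted <- report$predictions_converted + 1L
  }
  list(document = doc, report = report)
}

# ---- DNML -----------------------------------------------------------------

#' Convert DNML (XML) results
#'
#' DNML is the XML predecessor of this format: a tree of spectra and
#' single-score predictions. The single score becomes one named score;
#' spectra, their peaks and the prediction links are preserved. DNML has no
#' merged-spectra semantics, which the report notes.
#'
#' @param results Path to a DNML XML file.
#' @param mod_table Modification table for annotated sequences.
#' @return A list with elements `document` and `report`.
#' @export
convert_dnml <- function(results, mod_table = load_psimod()) {
  xml <- tryCatch(xml2::read_xml(results),
                  error = function(e) stop("parse error at /: ",
                                           conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(xml) != "dnml") {
    stop("parse error at /: root element is not <dnml>", call. = FALSE)
  }
  doc <- dnmso_document(creator = "dnmso dnml converter")
  doc <- add_software(doc, software("DNML", version = xml2::xml_attr(xml, "version") %||% ""))
  report <- new_report()
  report$lossiness <- "DNML carries no merged-spectra semantics"
  for (mn in xml2::xml_find_all(xml, "./modifications/modification")) {
    res <- xml2::xml_attr(mn, "residues")
    m <- modification(
      psimod_accession = xml2::xml_attr(mn, "accession"),
      name = ifelse(is.na(xml2::xml_attr(mn, "name")), "", xml2::xml_attr(mn, "name")),
      mono_mass_delta = as.numeric(xml2::xml_attr(mn, "monoDelta")),
      avg_mass_delta = suppressWarnings(as.numeric(xml2::xml_attr(mn, "avgDelta"))),
      residue_specificity = if (is.na(res) || identical(res, "any")) "any"
                            else strsplit(res, "")[[1]])
    if (is.null(doc$modifications[[m$local_id]])) doc <- add_modification(doc, m)
  }
  for (sn in xml2::xml_find_all(xml, "./spectra/spectrum")) {
    id <- xml2::xml_attr(sn, "id")
    if (is.na(id)) stop("parse error at /dnml/spectra/spectrum: missing id",
                        call. = FALSE)
    pk_txt <- xml2::xml_text(xml2::xml_find_first(sn, "./peaks"))
    pairs <- strsplit(trimws(pk_txt), "[ \t\n]+")[[1]]
    pairs <- pairs[nzchar(pairs)]
    mzint <- t(vapply(strsplit(pairs, ":", fixed = TRUE),
                      function(p) as.numeric(p), numeric(2)))
    ch <- xml2::xml_attr(sn, "charge")
    doc <- add_spectrum(doc, spectrum(
      precursor_mz = as.numeric(xml2::xml_attr(sn, "precursorMz")),
      precursor_charge = if (is.na(ch)) NA_integer_ else as.integer(ch),
      peaks = tibble::tibble(mz = mzint[, 1], intensity = mzint[, 2]),
      id = id, native_id = id, normalize = TRUE))
    report$spectra_read <- report$spectra_read + 1L
  }
  for (pn in xml2::xml_find_all(xml, "./predictions/prediction")) {
    report$records_seen <- report$records_seen + 1L
    refs <- strsplit(xml2::xml_attr(pn, "spectrumRefs") %||% "", "[ ]+")[[1]]
    refs <- refs[nzchar(refs)]
    seq_txt <- xml2::xml_text(xml2::xml_find_first(pn, "./sequence"))
    seq <- tryCatch(parse_sequence(seq_txt, doc$modifications),
                    error = function(e) e)
    if (inherits(seq, "error") || length(setdiff(refs, names(doc$spectra))) > 0 ||
        length(refs) == 0) {
      report$skipped <- report$skipped + 1L
      report$warnings <- c(report$warnings, paste0(
        "DNML prediction '", xml2::xml_attr(pn, "id") %||% "?", "' skipped"))
      next
    }
    rk <- xml2::xml_attr(pn, "rank")
    doc <- add_prediction(doc, prediction(
      sequence = seq,
      scores = score("score", as.numeric(xml2::xml_attr(pn, "score"))),
      source_spectrum_refs = refs, software_ref = "DNML",
      rank = if (is.na(rk)) NULL else as.integer(rk),
      id = xml2::xml_attr(pn, "id")))
    report$predictions_converted <- report$predictions_converted + 1L
  }
  list(document = doc, report = report)
}

#' Export a document to DNML (lossy)
#'
#' Minimal DNML writer used for subset-projection checks: keeps inline
#' spectra and predictions but only the first score, plain-style sequences
#' and no software/modification detail.
#'
#' @param doc A valid `dnmso_document` with inline spectra.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_dnml <- function(doc, path) {
  specs <- vapply(doc$spectra, function(s) {
    sprintf('<spectrum id="%s" precursorMz="%s"%s><peaks>%s</peaks></spectrum>',
            xml_escape(s$id), fmt_num(s$precursor_mz),
            if (!is.na(s$precursor_charge)) sprintf(' charge="%d"', s$precursor_charge) else "",
            paste(paste0(fmt_num(s$peaks$mz), ":", fmt_num(s$peaks$intensity)),
                  collapse = " "))
  }, character(1))
  preds <- vapply(doc$predictions, function(p) {
    sprintf('<prediction id="%s" spectrumRefs="%s" score="%s"%s><sequence>%s</sequence></prediction>',
            xml_escape(p$id), xml_escape(paste(p$source_spectrum_refs, collapse = " ")),
            fmt_num(p$scores[[1]]$value),
            if (!is.null(p$rank)) sprintf(' rank="%d"', p$rank) else "",
            xml_escape(render_sequence(p$sequence, "plain")))
  }, character(1))
  writeLines(sprintf(
    '<?xml version="1.0" encoding="utf-8"?>\n<dnml version="1.0"><spectra>%s</spectra><predictions>%s</predictions></dnml>\n',
    paste(specs, collapse = ""), paste(preds, collapse = "")), path, sep = "")
  invisible(path)
}

# ---- pepXML ---------------------------------------------------------------

#' Convert pepXML results
#'
#' Reads `spectrum_query`/`search_hit` elements: each hit becomes a
#' prediction with all `search_score` entries kept as named scores.
#' Positional modification masses (`mod_aminoacid_mass@mass`, the *total*
#' modified residue mass) are matched to the modification table by mass
#' delta within 0.01 Da; unmatched deltas become a `MOD:00000` placeholder
#' with a warning. Database/protein attributes are ignored with a lossiness
#' note — de novo sequencing has no database to represent.
#'
#' @inheritParams convert_pepnovo
#' @return A list with elements `document` and `report`.
#' @export
convert_pepxml <- function(results, spectra, mod_table = load_psimod()) {
  xml <- tryCatch(xml2::read_xml(results),
                  error = function(e) stop("parse error at /: ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(xml)
  stray <- xml2::xml_find_all(xml, ".//search_hit[not(ancestor::spectrum_query)]")
  if (length(stray) > 0) {
    stop("structural error: search_hit outside a spectrum_query", call. = FALSE)
  }
  sp <- as_spectra_list(spectra)
  doc <- seed_document(sp, creator = "dnmso pepxml converter")
  doc <- add_software(doc, software("pepXML-source", version = ""))
  report <- new_report()
  report$spectra_read <- length(sp)
  protein_seen <- FALSE
  for (q in xml2::xml_find_all(xml, ".//spectrum_query")) {
    title <- xml2::xml_attr(q, "spectrum")
    start_scan <- suppressWarnings(as.integer(xml2::xml_attr(q, "start_scan")))
    charge <- suppressWarnings(as.integer(xml2::xml_attr(q, "assumed_charge")))
    nmass <- suppressWarnings(as.numeric(xml2::xml_attr(q, "precursor_neutral_mass")))
    mz <- if (!is.na(nmass) && !is.na(charge)) (nmass + charge * MASS_PROTON) / charge else NA_real_
    for (hit in xml2::xml_find_all(q, ".//search_hit")) {
      report$records_seen <- report$records_seen + 1L
      if (!is.na(xml2::xml_attr(hit, "protein"))) protein_seen <- TRUE
      sid <- find_spectrum_id(doc, title = title, index = start_scan, mz = mz)
      if (is.null(sid)) {
        report$skipped <- report$skipped + 1L
        report$warnings <- c(report$warnings, paste0(
          "spectrum_query '", title, "' has no matching spectrum; hit skipped"))
        next
      }
      pept <- xml2::xml_attr(hit, "peptide")
      letters <- strsplit(pept, "")[[1]]
      mods_at <- list()
      for (mam in xml2::xml_find_all(hit, ".//mod_aminoacid_mass")) {
        posn <- as.integer(xml2::xml_attr(mam, "position"))
        total <- as.numeric(xml2::xml_attr(mam, "mass"))
        mods_at[[as.character(posn)]] <- total
      }
      els <- list()
      bad <- FALSE
      for (k in seq_along(letters)) {
        res <- letters[k]
        if (!res %in% names(AA_MONO)) { bad <- TRUE; break }
        total <- mods_at[[as.character(k)]]
        if (is.null(total)) {
          els[[length(els) + 1L]] <- aa(res)
        } else {
          delta <- total - residue_mono_mass(res)
          r2 <- resolve_delta_mod(doc, report, res, delta, mod_table)
          doc <- r2$doc; report <- r2$report
          els[[length(els) + 1L]] <- mod_aa(res, r2$ref)
        }
      }
      if (bad || length(els) == 0) {
        report$skipped <- report$skipped + 1L
        report$warnings <- c(report$warnings,
                             paste0("unparseable peptide '", pept, "' skipped"))
        next
      }
      scores <- lapply(xml2::xml_find_all(hit, ".//search_score"), function(sn) {
        score(xml2::xml_attr(sn, "name"), as.numeric(xml2::xml_attr(sn, "value")))
      })
      if (length(scores) == 0) {
        report$skipped <- report$skipped + 1L
        report$warnings <- c(report$warnings,
                             paste0("hit for '", title, "' has no search_score; skipped"))
        next
      }
      rk <- suppressWarnings(as.integer(xml2::xml_attr(hit, "hit_rank")))
      doc <- add_prediction(doc, prediction(
        sequence = do.call(pep_sequence, els), scores = scores,
        source_spectrum_refs = sid, software_ref = "pepXML-source",
        rank = if (is.na(rk)) NULL else rk))
      report$predictions_converted <- report$predictions_converted + 1L
    }
  }
  if (protein_seen) {
    report$lossiness <- c(report$lossiness, "protein fields dropped")
  }
  list(document = doc, report = report)
}

# ---- PEAKS-style CSV ------------------------------------------------------

PEAKS_HEADER <- c("Scan", "Peptide", "ALC", "m/z", "z")

#' Convert a PEAKS-style CSV export
#'
#' PEAKS itself writes proprietary project files; supported here is a
#' documented CSV export dialect with columns `Scan,Peptide,ALC,m/z,z`.
#' Peptides may carry `(+delta)` residue annotations; `ALC` becomes the
#' single score.
#'
#' @inheritParams convert_pepnovo
#' @return A list with elements `document` and `report`.
#' @export
convert_peaks_csv <- function(results, spectra, mod_table = load_psimod()) {
  sp <- as_spectra_list(spectra)
  doc <- seed_document(sp, creator = "dnmso peaks-csv converter")
  doc <- add_software(doc, software("PEAKS", version = "csv-dialect"))
  report <- new_report()
  report$spectra_read <- length(sp)
  tab <- utils::read.csv(results, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(tab), PEAKS_HEADER)) {
    stop("dialect error: unknown PEAKS CSV layout; expected columns ",
         paste(PEAKS_HEADER, collapse = ","), call. = FALSE)
  }
  for (k in seq_len(nrow(tab))) {
    report$records_seen <- report$records_seen + 1L
    sid <- find_spectrum_id(doc, title = as.character(tab$Scan[k]),
                            index = suppressWarnings(as.integer(tab$Scan[k])),
                            mz = tab[["m/z"]][k])
    parsed <- tryCatch(parse_tool_sequence(doc, report, tab$Peptide[k], mod_table),
                       error = function(e) e)
    if (is.null(sid) || inherits(parsed, "error")) {
      report$skipped <- report$skipped + 1L
      report$warnings <- c(report$warnings,
                           paste0("PEAKS row ", k, " skipped"))
      next
    }
    doc <- parsed$doc; report <- parsed$report
    doc <- add_prediction(doc, prediction(
      sequence = parsed$seq, scores = score("ALC", as.numeric(tab$ALC[k])),
      source_spectrum_refs = sid, software_ref = "PEAKS"))
    report$predictions_converted <- report$predictions_converted + 1L
  }
  list(document = doc, report = report)
}

# ---- mzIdentML export -----------------------------------------------------

#' Export a document to mzIdentML (lossy, write-only)
#'
#' Emits 1.1-style element structure: one `SpectrumIdentificationResult` per
#' spectrum with predictions and one `SpectrumIdentificationItem` per
#' prediction, carrying every score as a `cvParam` (when a CV accession is
#' present) or `userParam`. No protein or database sections are written.
#' mzIdentML peptide sequences cannot hold mass gaps or per-element
#' evidence, so the full plain rendering (gaps in parentheses), per-element
#' confidences and extra source-spectrum links appear only as `userParam`
#' entries — the export is lossy by design and there is no importer.
#'
#' @param doc A valid `dnmso_document`.
#' @return A single string of mzIdentML XML.
#' @export
export_mzidentml <- function(doc) {
  stopifnot(inherits(doc, "dnmso_document"))
  if (n_errors(doc) > 0) {
    stop("refusing to export an invalid document", call. = FALSE)
  }
  peptides <- character(0)
  items_by_spec <- list()
  for (p in doc$predictions) {
    plain_letters <- vapply(p$sequence$elements, function(el) {
      if (el$kind %in% c("aa", "mod_aa")) el$residue else ""
    }, character(1))
    pep_id <- paste0("PEP_", enc_id(p$id))
    mods_xml <- ""
    loc <- 0L
    for (el in p$sequence$elements) {
      if (el$kind %in% c("aa", "mod_aa")) loc <- loc + 1L
      if (el$kind == "mod_aa") {
        m <- doc$modifications[[el$modification_ref]]
        mods_xml <- paste0(mods_xml, sprintf(
          '<Modification location="%d" monoisotopicMassDelta="%s"><cvParam cvRef="PSI-MOD" accession="%s" name="%s"/></Modification>',
          loc, fmt_num(m$mono_mass_delta), m$psimod_accession, xml_escape(m$name)))
      }
    }
    peptides <- c(peptides, sprintf(
      '<Peptide id="%s"><PeptideSequence>%s</PeptideSequence>%s</Peptide>',
      pep_id, paste(plain_letters, collapse = ""), mods_xml))
    params <- vapply(p$scores, function(s) {
      if (!is.null(s$cv_accession)) {
        sprintf('<cvParam cvRef="PSI-MS" accession="%s" name="%s" value="%s"/>',
                s$cv_accession, xml_escape(s$name), fmt_num(s$value))
      } else {
        sprintf('<userParam name="%s" value="%s"/>', xml_escape(s$name),
                fmt_num(s$value))
      }
    }, character(1))
    params <- c(params, sprintf(
      '<userParam name="de novo sequence" value="%s"/>',
      xml_escape(render_sequence(p$sequence, "plain"))))
    confs <- vapply(p$sequence$elements, function(el) el$confidence %||% NA_real_,
                    numeric(1))
    if (any(!is.na(confs))) {
      params <- c(params, sprintf(
        '<userParam name="per-element confidence" value="%s"/>',
        paste(ifelse(is.na(confs), "", fmt_num(confs)), collapse = ";")))
    }
    home <- p$source_spectrum_refs[1]
    if (length(p$source_spectrum_refs) > 1) {
      params <- c(params, sprintf(
        '<userParam name="additional source spectra" value="%s"/>',
        xml_escape(paste(p$source_spectrum_refs[-1], collapse = ";"))))
    }
    s <- doc$spectra[[home]]
    item <- sprintf(
      '<SpectrumIdentificationItem id="SII_%s" rank="%d"%s%s peptide_ref="%s" passThreshold="true">%s</SpectrumIdentificationItem>',
      enc_id(p$id), p$rank %||% 1L,
      if (!is.na(s$precursor_charge)) sprintf(' chargeState="%d"', s$precursor_charge) else "",
      if (!is.na(s$precursor_mz)) sprintf(' experimentalMassToCharge="%s"', fmt_num(s$precursor_mz)) else "",
      pep_id, paste(params, collapse = ""))
    items_by_spec[[home]] <- c(items_by_spec[[home]], item)
  }
  results <- vapply(names(items_by_spec), function(sid) {
    s <- doc$spectra[[sid]]
    sprintf('<SpectrumIdentificationResult id="SIR_%s" spectrumID="%s">%s</SpectrumIdentificationResult>',
            enc_id(sid), xml_escape(s$native_id %||% s$id),
            paste(items_by_spec[[sid]], collapse = ""))
  }, character(1))
  sw <- vapply(doc$software, function(w) {
    sprintf('<AnalysisSoftware id="AS_%s" name="%s" version="%s"/>',
            enc_id(w$id), xml_escape(w$name), xml_escape(w$version))
  }, character(1))
  paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<MzIdentML xmlns="http://psidev.info/psi/pi/mzIdentML/1.1" version="1.1.0" id="',
    xml_escape(doc$id), '">',
    '<cvList><cv id="PSI-MS" fullName="PSI-MS" uri="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="PSI-MOD" fullName="PSI-MOD" uri="https://raw.githubusercontent.com/HUPO-PSI/psi-mod-CV/master/PSI-MOD.obo"/></cvList>',
    '<AnalysisSoftwareList>', paste(sw, collapse = ""), '</AnalysisSoftwareList>',
    '<SequenceCollection>', paste(peptides, collapse = ""), '</SequenceCollection>',
    '<DataCollection><AnalysisData><SpectrumIdentificationList id="SIL_1">',
    paste(results, collapse = ""),
    '</SpectrumIdentificationList></AnalysisData></DataCollection>',
    '</MzIdentML>\n')
}

# ---- registry -------------------------------------------------------------

.converters <- new.env(parent = emptyenv())

ensure_default_converters <- function() {
  if (length(ls(.converters)) > 0) return(invisible())
  assign("pepnovo", list(fn = convert_pepnovo, needs_spectra = TRUE,
                         description = "PepNovo flat text (frozen dialect)"), .converters)
  assign("lutefisk", list(fn = convert_lutefisk, needs_spectra = TRUE,
                          description = "Lutefisk flat text (frozen dialect)"), .converters)
  assign("dnml", list(fn = function(results, spectra = NULL, mod_table = load_psimod())
                        convert_dnml(results, mod_table),
                      needs_spectra = FALSE,
                      description = "DNML XML (predecessor format)"), .converters)
  assign("pepxml", list(fn = convert_pepxml, needs_spectra = TRUE,
                        description = "pepXML search results"), .converters)
  assign("peaks-csv", list(fn = convert_peaks_csv, needs_spectra = TRUE,
                           description = "PEAKS-style CSV export dialect"), .converters)
  invisible()
}

#' Converter registry
#'
#' Converters are registered by name and can be added at runtime without
#' rebuilding the package. `convert()` dispatches by name;
#' `list_converters()` lists the registry.
#'
#' @param name Unique converter name.
#' @param fn Function `(results, spectra, mod_table) -> list(document, report)`.
#' @param description One-line description.
#' @param needs_spectra Does the converter require companion spectra?
#' @return `register_converter()`: the name, invisibly; `list_converters()`:
#'   a tibble; `convert()`: a list with `document` and `report`.
#' @export
register_converter <- function(name, fn, description = "", needs_spectra = TRUE) {
  ensure_default_converters()
  if (exists(name, envir = .converters, inherits = FALSE)) {
    stop("identity-conflict error: converter '", name, "' already registered",
         call. = FALSE)
  }
  assign(name, list(fn = fn, needs_spectra = needs_spectra,
                    description = description), .converters)
  invisible(name)
}

#' @rdname register_converter
#' @export
list_converters <- function() {
  ensure_default_converters()
  nm <- sort(ls(.converters))
  tibble::tibble(
    name = nm,
    needs_spectra = vapply(nm, function(n) get(n, .converters)$needs_spectra, logical(1)),
    description = vapply(nm, function(n) get(n, .converters)$description, character(1))
  )
}

#' @rdname register_converter
#' @param from Registered converter name.
#' @param results Results file path.
#' @param spectra Companion spectra (path or list), when required.
#' @param mod_table Modification table.
#' @export
convert <- function(from, results, spectra = NULL, mod_table = load_psimod()) {
  ensure_default_converters()
  if (!exists(from, envir = .converters, inherits = FALSE)) {
    stop("unknown converter '", from, "'; registered: ",
         paste(sort(ls(.converters)), collapse = ", "), call. = FALSE)
  }
  entry <- get(from, .converters)
  if (entry$needs_spectra) entry$fn(results, spectra, mod_table)
  else entry$fn(results, spectra = spectra, mod_table = mod_table)
}
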