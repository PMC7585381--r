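# Rule-based validation. Instead of OWL reasoning, the structural invariants
# of the model are checked by deterministic rules; each violation names the
# rule, a severity and the offending element. ERROR marks constraints the
# format mandates (a prediction must have spectra and scores; every PTM must
# reference a PSI-MOD term); WARNING marks advisory checks.

violation_row <- function(rule, severity, message, element) {
  tibble::tibble(rule = rule, severity = severity, message = message,
                 element = element)
}

#' Validate a document against the model invariants
#'
#' Checks every structural invariant of the document, spectrum, prediction
#' and sequence model and returns the violations as a tibble (never raises).
#' A document built exclusively through the guarded `add_*` operations
#' validates clean; documents deserialized from files may not.
#'
#' Rules (severity ERROR unless noted): `orphan_prediction`, `missing_score`,
#' `dangling_spectrum_ref`, `dangling_modification_ref`, `missing_psimod`,
#' `unsorted_peaks`, `bad_peak_values`, `spectrum_no_data`, `duplicate_id`,
#' `empty_sequence`, `bad_residue`, `bad_confidence`,
#' `dangling_supporting_peak`, `bad_cv_accession`; WARNING:
#' `dangling_software_ref`, `empty_provenance`, `unknown_cv_ref`.
#'
#' @param doc A `dnmso_document`.
#' @return A tibble with columns `rule`, `severity`, `message`, `element`,
#'   ordered by offending element id; zero rows iff the document is valid.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "dnmso_document"))
  v <- list()
  add <- function(rule, severity, message, element) {
    v[[length(v) + 1L]] <<- violation_row(rule, severity, message, element)
  }

  for (pool in list(doc$spectra, doc$predictions, doc$modifications,
                    doc$software, doc$cv_registry)) {
    ids <- names(pool)
    for (dup in unique(ids[duplicated(ids)])) {
      add("duplicate_id", "ERROR",
          paste0("local id '", dup, "' is not unique within its collection"), dup)
    }
  }

  for (id in names(doc$spectra)) {
    s <- doc$spectra[[id]]
    if (nrow(s$peaks) == 0 && is.null(s$external_ref)) {
      add("spectrum_no_data", "ERROR",
          paste0("spectrum '", id, "' has neither inline peaks nor an external reference"), id)
    }
    if (nrow(s$peaks) > 0) {
      if (any(!is.finite(s$peaks$mz)) || any(!is.finite(s$peaks$intensity)) ||
          any(s$peaks$mz <= 0) || any(s$peaks$intensity < 0)) {
        add("bad_peak_values", "ERROR",
            paste0("spectrum '", id, "' has non-finite, non-positive m/z or negative intensity peaks"), id)
      } else if (is.unsorted(s$peaks$mz)) {
        add("unsorted_peaks", "ERROR",
            paste0("spectrum '", id, "' peaks are not sorted by ascending m/z"), id)
      }
    }
    if (!is.null(s$external_ref) && !nzchar(s$external_ref$native_id %||% "")) {
      add("bad_external_ref", "ERROR",
          paste0("spectrum '", id, "' external reference lacks a native id"), id)
    }
  }

  for (id in names(doc$predictions)) {
    p <- doc$predictions[[id]]
    if (length(p$source_spectrum_refs) == 0) {
      add("orphan_prediction", "ERROR",
          paste0("prediction '", id, "' has no source spectra (predictions without associated spectra are not allowed)"), id)
    } else {
      dangling <- setdiff(p$source_spectrum_refs, names(doc$spectra))
      for (d in dangling) {
        add("dangling_spectrum_ref", "ERROR",
            paste0("prediction '", id, "' references unknown spectrum '", d, "'"), id)
      }
    }
    if (length(p$scores) == 0) {
      add("missing_score", "ERROR",
          paste0("prediction '", id, "' carries no score (at least one is required)"), id)
    }
    if (!is.null(p$software_ref) && is.null(doc$software[[p$software_ref]])) {
      add("dangling_software_ref", "WARNING",
          paste0("prediction '", id, "' references unknown software '", p$software_ref, "'"), id)
    }
    v <- c(v, validate_sequence_in_doc(doc, p$sequence, id))
  }

  for (id in names(doc$modifications)) {
    m <- doc$modifications[[id]]
    if (is.null(m$psimod_accession) || !grepl(PSIMOD_PATTERN, m$psimod_accession %||% "")) {
      add("missing_psimod", "ERROR",
          paste0("modification '", id, "' lacks a well-formed PSI-MOD accession (MOD:\\d{5})"), id)
    }
    if (!is.finite(m$mono_mass_delta %||% NA_real_)) {
      add("bad_mass_delta", "ERROR",
          paste0("modification '", id, "' has a non-finite monoisotopic mass delta"), id)
    }
  }

  for (id in names(doc$software)) {
    sw <- doc$software[[id]]
    for (pp in sw$parameters) {
      if (inherits(pp, "dnmso_cv_param")) {
        if (!grepl("^[A-Za-z][A-Za-z0-9-]*:[0-9]+$", pp$accession %||% "")) {
          add("bad_cv_accession", "ERROR",
              paste0("software '", id, "' has cvParam with malformed accession '",
                     pp$accession %||% "", "'"), id)
        }
        if (!is.null(pp$cv_ref) && is.null(doc$cv_registry[[pp$cv_ref]])) {
          add("unknown_cv_ref", "WARNING",
              paste0("software '", id, "' cvParam references unregistered CV '",
                     pp$cv_ref, "'"), id)
        }
      }
    }
  }

  if (!nzchar(doc$provenance$creator %||% "")) {
    add("empty_provenance", "WARNING", "document provenance has no creator", doc$id)
  }

  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0) {
    return(violation_row(character(0), character(0), character(0), character(0)))
  }
  out[order(out$element, out$rule), , drop = FALSE]
}

validate_sequence_in_doc <- function(doc, seq, pred_id) {
  v <- list()
  add <- function(rule, severity, message) {
    v[[length(v) + 1L]] <<- violation_row(rule, severity, message, pred_id)
  }
  if (!inherits(seq, "dnmso_sequence") || seq_length(seq) == 0) {
    add("empty_sequence", "ERROR",
        paste0("prediction '", pred_id, "' has an empty sequence"))
    return(v)
  }
  for (k in seq_len(seq_length(seq))) {
    el <- seq$elements[[k]]
    if (el$kind %in% c("aa", "mod_aa") && !el$residue %in% names(AA_MONO)) {
      add("bad_residue", "ERROR",
          sprintf("prediction '%s' element %d has residue '%s' outside the canonical alphabet",
                  pred_id, k, el$residue))
    }
    if (el$kind == "mod_aa") {
      m <- doc$modifications[[el$modification_ref]]
      if (is.null(m)) {
        add("dangling_modification_ref", "ERROR",
            sprintf("prediction '%s' element %d references unknown modification '%s'",
                    pred_id, k, el$modification_ref))
      }
    }
    if (el$kind == "gap" && (!is.finite(el$mass) || el$mass <= 0)) {
      add("bad_gap_mass", "ERROR",
          sprintf("prediction '%s' element %d has a non-positive gap mass", pred_id, k))
    }
    if (!is.null(el$confidence) &&
        (el$confidence < 0 || el$confidence > 1 || !is.finite(el$confidence))) {
      add("bad_confidence", "ERROR",
          sprintf("prediction '%s' element %d confidence outside [0, 1]", pred_id, k))
    }
    if (!is.null(el$supporting_peaks) && nrow(el$supporting_peaks) > 0) {
      for (r in seq_len(nrow(el$supporting_peaks))) {
        sid <- el$supporting_peaks$spectrum_id[r]
        idx <- el$supporting_peaks$peak_index[r]
        s <- doc$spectra[[sid]]
        if (is.null(s) || idx < 1 || idx > nrow(s$peaks)) {
          add("dangling_supporting_peak", "ERROR",
              sprintf("prediction '%s' element %d cites peak %d of unknown spectrum/peak '%s'",
                      pred_id, k, idx, sid))
        }
      }
    }
  }
  v
}

#' Count ERROR-severity violations
#'
#' @param doc A `dnmso_document`.
#' @return Integer count of ERROR violations.
#' @export
n_errors <- function(doc) {
  v <- validate_document(doc)
  sum(v$severity == "ERROR")
}
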