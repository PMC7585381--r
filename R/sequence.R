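# Sequence elements: a de novo predicted sequence is an ordered run of amino
# acids, modified amino acids and mass gaps. Each element may carry a
# confidence in [0, 1] and supporting-peak evidence (spectrum id + peak index).

new_element <- function(kind, residue = NULL, modification_ref = NULL,
                        mass = NULL, confidence = NULL, supporting_peaks = NULL) {
  if (!is.null(confidence)) {
    if (!is.numeric(confidence) || length(confidence) != 1 || is.na(confidence) ||
        confidence < 0 || confidence > 1) {
      stop("confidence must be a single number in [0, 1]", call. = FALSE)
    }
    confidence <- as.numeric(confidence)
  }
  if (!is.null(supporting_peaks)) {
    supporting_peaks <- tibble::as_tibble(supporting_peaks)
    if (!all(c("spectrum_id", "peak_index") %in% names(supporting_peaks))) {
      stop("supporting_peaks needs columns spectrum_id, peak_index", call. = FALSE)
    }
    supporting_peaks <- supporting_peaks[, c("spectrum_id", "peak_index")]
    supporting_peaks$spectrum_id <- as.character(supporting_peaks$spectrum_id)
    supporting_peaks$peak_index <- as.integer(supporting_peaks$peak_index)
  }
  structure(
    list(kind = kind, residue = residue, modification_ref = modification_ref,
         mass = mass, confidence = confidence, supporting_peaks = supporting_peaks),
    class = c(paste0("dnmso_", kind), "dnmso_element")
  )
}

#' Sequence element constructors
#'
#' `aa()` builds a plain amino-acid element, `mod_aa()` a modified amino acid
#' carrying a reference to a [modification()] registered in the document, and
#' `gap()` a mass gap — a contiguous unexplained stretch of the peptide given
#' only by its monoisotopic mass.
#'
#' @param residue Single uppercase letter from the 20 standard amino acids.
#' @param modification_ref Local id of a modification in the document's
#'   modification table.
#' @param mass Gap mass in Daltons (monoisotopic), strictly positive.
#' @param confidence Optional per-element confidence in `[0, 1]`.
#' @param supporting_peaks Optional data frame with columns `spectrum_id`,
#'   `peak_index` giving the peaks that support this element.
#' @return A sequence element object.
#' @examples
#' aa("G")
#' gap(100.0)
#' @export
aa <- function(residue, confidence = NULL, supporting_peaks = NULL) {
  residue_mono_mass(residue) # validates the alphabet
  new_element("aa", residue = residue, confidence = confidence,
              supporting_peaks = supporting_peaks)
}

#' @rdname aa
#' @export
mod_aa <- function(residue, modification_ref, confidence = NULL,
                   supporting_peaks = NULL) {
  residue_mono_mass(residue)
  if (!is.character(modification_ref) || length(modification_ref) != 1 ||
      !nzchar(modification_ref)) {
    stop("modification_ref must be a non-empty string", call. = FALSE)
  }
  new_element("mod_aa", residue = residue, modification_ref = modification_ref,
              confidence = confidence, supporting_peaks = supporting_peaks)
}

#' @rdname aa
#' @export
gap <- function(mass, confidence = NULL, supporting_peaks = NULL) {
  if (!is.numeric(mass) || length(mass) != 1 || !is.finite(mass) || mass <= 0) {
    stop("gap mass must be a finite positive number of Daltons", call. = FALSE)
  }
  new_element("gap", mass = as.numeric(mass), confidence = confidence,
              supporting_peaks = supporting_peaks)
}

#' Build a sequence from elements
#'
#' A sequence is a non-empty ordered list of elements built with [aa()],
#' [mod_aa()] and [gap()]. A string of plain residue letters is also accepted
#' as shorthand.
#'
#' @param ... Sequence elements, or a single character string of residues.
#' @return A `dnmso_sequence`.
#' @examples
#' pep_sequence("PEPTIDE")
#' pep_sequence(aa("G"), gap(100), aa("A"))
#' @export
pep_sequence <- function(...) {
  els <- list(...)
  if (length(els) == 1 && is.character(els[[1]])) {
    letters <- strsplit(els[[1]], "")[[1]]
    els <- lapply(letters, aa)
  }
  if (length(els) == 0) stop("a sequence must have at least one element", call. = FALSE)
  ok <- vapply(els, inherits, logical(1), "dnmso_element")
  if (!all(ok)) stop("all sequence parts must be sequence elements", call. = FALSE)
  structure(list(elements = els), class = "dnmso_sequence")
}

seq_length <- function(seq) length(seq$elements)

#' Neutral monoisotopic mass of a sequence
#'
#' Sums residue masses (plus modification deltas for modified residues) and
#' gap masses over the elements, then adds one water for the peptide termini.
#' The result is the neutral (uncharged) peptide mass in Daltons.
#'
#' @param seq A [pep_sequence()].
#' @param modifications Named list of [modification()] objects keyed by local
#'   id (e.g. `doc$modifications`); required when the sequence contains
#'   modified residues.
#' @return Neutral monoisotopic mass in Daltons.
#' @examples
#' sequence_mono_mass(pep_sequence(gap(100)))  # 118.010565
#' @export
sequence_mono_mass <- function(seq, modifications = list()) {
  stopifnot(inherits(seq, "dnmso_sequence"))
  total <- MASS_WATER
  for (el in seq$elements) {
    total <- total + switch(el$kind,
      aa = residue_mono_mass(el$residue),
      gap = el$mass,
      mod_aa = {
        m <- modifications[[el$modification_ref]]
        if (is.null(m)) {
          stop("unresolved-reference error: modification '", el$modification_ref,
               "' not found", call. = FALSE)
        }
        residue_mono_mass(el$residue) + m$mono_mass_delta
      }
    )
  }
  total
}

format_gap_mass <- function(mass) sprintf("(%.5f)", mass)

#' Render a sequence as text
#'
#' Plain style prints residue letters, drops modification annotations, and
#' prints gaps as the unexplained mass in parentheses, e.g. `"G(100.00000)A"`.
#' Annotated style additionally tags each modified residue with its PSI-MOD
#' accession, e.g. `"S[MOD:00046]"`; stripping the bracketed annotations from
#' annotated output yields the plain rendering.
#'
#' @inheritParams sequence_mono_mass
#' @param style `"plain"` or `"annotated"`.
#' @return A single string.
#' @export
render_sequence <- function(seq, style = c("plain", "annotated"),
                            modifications = list()) {
  style <- match.arg(style)
  stopifnot(inherits(seq, "dnmso_sequence"))
  parts <- vapply(seq$elements, function(el) {
    switch(el$kind,
      aa = el$residue,
      gap = format_gap_mass(el$mass),
      mod_aa = {
        if (style == "plain") return(el$residue)
        m <- modifications[[el$modification_ref]]
        acc <- if (!is.null(m)) m$psimod_accession else el$modification_ref
        paste0(el$residue, "[", acc, "]")
      }
    )
  }, character(1))
  paste(parts, collapse = "")
}

#' Parse a rendered sequence
#'
#' Inverse of [render_sequence()]: accepts plain or annotated style. Gap
#' masses accept any decimal precision. Annotated modifications
#' (`X[MOD:00046]`) are resolved against `modifications` by PSI-MOD accession
#' (falling back to local id).
#'
#' @param text Rendered sequence text.
#' @param modifications Named list of [modification()] objects keyed by local
#'   id, used to resolve annotated accessions.
#' @return A `dnmso_sequence`.
#' @export
parse_sequence <- function(text, modifications = list()) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("syntax error: empty sequence text", call. = FALSE)
  }
  els <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "(") {
      close <- find_closing(text, i, "(", ")")
      body <- substr(text, i + 1L, close - 1L)
      mass <- suppressWarnings(as.numeric(body))
      if (is.na(mass)) stop("syntax error: bad gap mass '", body, "'", call. = FALSE)
      els[[length(els) + 1L]] <- gap(mass)
      i <- close + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      nxt <- if (i < n) substr(text, i + 1L, i + 1L) else ""
      if (nxt == "[") {
        close <- find_closing(text, i + 1L, "[", "]")
        acc <- substr(text, i + 2L, close - 1L)
        ref <- resolve_accession_to_ref(acc, modifications)
        els[[length(els) + 1L]] <- mod_aa(ch, ref)
        i <- close + 1L
      } else {
        els[[length(els) + 1L]] <- aa(ch)
        i <- i + 1L
      }
    } else {
      stop("syntax error: unexpected character '", ch, "' at position ", i,
           call. = FALSE)
    }
  }
  do.call(pep_sequence, els)
}

find_closing <- function(text, open_at, open, close) {
  rest <- substr(text, open_at + 1L, nchar(text))
  pos <- regexpr(close, rest, fixed = TRUE)
  if (pos < 0) stop("syntax error: unbalanced '", open, "' at position ",
                    open_at, call. = FALSE)
  open_at + as.integer(pos)
}

resolve_accession_to_ref <- function(acc, modifications) {
  if (!is.null(modifications[[acc]])) return(acc)
  for (id in names(modifications)) {
    if (identical(modifications[[id]]$psimod_accession, acc)) return(id)
  }
  stop("unresolved-modification error: no modification for accession '",
       acc, "'", call. = FALSE)
}

#' @export
print.dnmso_sequence <- function(x, ...) {
  cat("<dnmso sequence> ", render_sequence(x), " (", seq_length(x),
      " elements)\n", sep = "")
  invisible(x)
}

#' @export
format.dnmso_sequence <- function(x, ...) render_sequence(x)

# Structural equality between sequences, elementwise; used by the round-trip
# oracle. Compares kinds, residues, refs, gap masses, confidences and
# supporting peaks.
sequences_identical <- function(a, b) {
  if (seq_length(a) != seq_length(b)) return(FALSE)
  for (k in seq_len(seq_length(a))) {
    x <- a$elements[[k]]; y <- b$elements[[k]]
    if (!identical(x$kind, y$kind)) return(FALSE)
    if (!identical(x$residue, y$residue)) return(FALSE)
    if (!identical(x$modification_ref, y$modification_ref)) return(FALSE)
    if (!isTRUE(all.equal(x$mass, y$mass)) && !(is.null(x$mass) && is.null(y$mass))) return(FALSE)
    if (!identical(is.null(x$confidence), is.null(y$confidence))) return(FALSE)
    if (!is.null(x$confidence) && x$confidence != y$confidence) return(FALSE)
    spx <- x$supporting_peaks; spy <- y$supporting_peaks
    if (!identical(is.null(spx), is.null(spy))) return(FALSE)
    if (!is.null(spx) && !identical(as.data.frame(spx), as.data.frame(spy))) return(FALSE)
  }
  TRUE
}

# Strip modifications: every modified amino acid reduces to its plain residue.
demodify_sequence <- function(seq) {
  els <- lapply(seq$elements, function(el) {
    if (el$kind == "mod_aa") {
      new_element("aa", residue = el$residue, confidence = el$confidence,
                  supporting_peaks = el$supporting_peaks)
    } else el
  })
  do.call(pep_sequence, els)
}
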