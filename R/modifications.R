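# Post-translational modifications. Every modification carried by a document
# must reference a PSI-MOD term by accession; instances also record the mono-
# isotopic and average mass deltas so files remain usable standalone.

PSIMOD_PATTERN <- "^MOD:[0-9]{5}$"

#' Create a modification entry
#'
#' A document stores only the modifications it actually uses; each must
#' reference a PSI-MOD ontology term (`MOD:` accession) and carry its own
#' monoisotopic and average mass deltas so that instances are interpretable
#' without the full ontology.
#'
#' @param psimod_accession PSI-MOD accession, pattern `MOD:\\d{5}`. Required.
#' @param name Human-readable modification name.
#' @param mono_mass_delta Monoisotopic mass shift in Daltons (finite; may be
#'   negative, e.g. pyroglutamate formation).
#' @param avg_mass_delta Average mass shift in Daltons.
#' @param residue_specificity Character vector of residue letters the
#'   modification applies to, or `"any"`.
#' @param terminus `"none"`, `"N-term"` or `"C-term"`.
#' @param local_id Local id within the document; defaults to the accession.
#' @return A `dnmso_modification`.
#' @examples
#' modification("MOD:00046", "O-phospho-L-serine", 79.966331, 79.9799, "S")
#' @export
modification <- function(psimod_accession, name = "", mono_mass_delta,
                         avg_mass_delta = NA_real_,
                         residue_specificity = "any",
                         terminus = c("none", "N-term", "C-term"),
                         local_id = psimod_accession) {
  terminus <- match.arg(terminus)
  if (!is.character(psimod_accession) || length(psimod_accession) != 1 ||
      !grepl(PSIMOD_PATTERN, psimod_accession)) {
    stop("modification requires a PSI-MOD accession matching MOD:\\d{5}",
         call. = FALSE)
  }
  if (!is.numeric(mono_mass_delta) || !is.finite(mono_mass_delta)) {
    stop("mono_mass_delta must be finite", call. = FALSE)
  }
  structure(
    list(local_id = local_id, psimod_accession = psimod_accession,
         name = name, mono_mass_delta = as.numeric(mono_mass_delta),
         avg_mass_delta = as.numeric(avg_mass_delta),
         residue_specificity = residue_specificity, terminus = terminus),
    class = "dnmso_modification"
  )
}

#' @export
print.dnmso_modification <- function(x, ...) {
  cat(sprintf("<modification %s> %s (mono %+0.6f Da, %s)\n", x$psimod_accession,
              x$name, x$mono_mass_delta,
              paste(x$residue_specificity, collapse = "")), sep = "")
  invisible(x)
}

#' Load the bundled PSI-MOD subset table
#'
#' The package ships a small curated subset of common modifications (a
#' synthetic excerpt following PSI-MOD conventions, not the full ontology) as
#' a TSV with columns `accession`, `name`, `mono_delta`, `avg_delta`,
#' `residues`, `terminus`. The full ontology can be loaded from a
#' user-supplied OBO file with [read_psimod_obo()].
#'
#' @param path Optional path to an alternative table in the same layout.
#' @return A tibble, one row per modification term.
#' @export
load_psimod <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "psimod_subset.tsv", package = "dnmso")
  }
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' Read PSI-MOD terms from an OBO file
#'
#' Minimal OBO reader extracting, per `[Term]` stanza, the accession, name,
#' `DiffMono`/`DiffAvg` mass-delta xrefs and `Origin`/`TermSpec` specificity
#' xrefs. Terms without a monoisotopic delta are dropped.
#'
#' @param path Path to an OBO file.
#' @return A tibble in the [load_psimod()] layout.
#' @export
read_psimod_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  rows <- list()
  for (k in seq_along(term_starts)) {
    from <- term_starts[k] + 1L
    to <- if (k < length(term_starts)) term_starts[k + 1L] - 1L else length(lines)
    block <- lines[from:to]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(hit) == 0) NA_character_ else sub(paste0("^", key, ": "), "", hit[1])
    }
    xref <- function(key) {
      hit <- grep(paste0('^xref: ', key, ': "'), block, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      sub('.*: "([^"]*)".*', "\\1", hit[1])
    }
    id <- get1("id")
    mono <- suppressWarnings(as.numeric(xref("DiffMono")))
    if (is.na(id) || is.na(mono)) next
    origin <- xref("Origin")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      accession = id,
      name = get1("name"),
      mono_delta = mono,
      avg_delta = suppressWarnings(as.numeric(xref("DiffAvg"))),
      residues = if (is.na(origin) || origin == "X") "any" else gsub(", ", "", origin),
      terminus = switch(xref("TermSpec"),
                        "N-term" = "N-term", "C-term" = "C-term", "none")
    )
  }
  dplyr::bind_rows(rows)
}

#' Look up a modification by accession or name
#'
#' Accession queries (pattern `MOD:\\d{5}`) must match exactly one row; name
#' queries return a match only when unique.
#'
#' @param query A PSI-MOD accession or a modification name.
#' @param table A table from [load_psimod()] or [read_psimod_obo()].
#' @return A [modification()] object (local id = accession).
#' @export
resolve_modification <- function(query, table = load_psimod()) {
  if (!is.character(query) || length(query) != 1 || !nzchar(query)) {
    stop("syntax error: empty modification query", call. = FALSE)
  }
  hits <- if (grepl("^MOD:", query)) {
    table[table$accession == query, , drop = FALSE]
  } else {
    table[table$name == query, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    stop("unresolved-modification error: no PSI-MOD entry for '", query, "'",
         call. = FALSE)
  }
  if (nrow(hits) > 1) {
    stop("ambiguity error: '", query, "' matches ",
         nrow(hits), " entries", call. = FALSE)
  }
  row_to_modification(hits[1, ])
}

row_to_modification <- function(row) {
  res <- row$residues
  res <- if (identical(res, "any")) "any" else strsplit(res, "")[[1]]
  modification(
    psimod_accession = row$accession, name = row$name,
    mono_mass_delta = row$mono_delta, avg_mass_delta = row$avg_delta,
    residue_specificity = res,
    terminus = if (row$terminus %in% c("N-term", "C-term")) row$terminus else "none"
  )
}

# Find a modification in the table whose mono delta matches `delta` within
# `tol` Daltons, preferring residue-specific entries for `residue`. Used by
# converters mapping positional mass offsets. Returns NULL when nothing
# matches.
match_modification_by_delta <- function(delta, residue = NULL,
                                        table = load_psimod(), tol = 0.01) {
  cand <- table[abs(table$mono_delta - delta) <= tol, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  if (!is.null(residue)) {
    specific <- cand[vapply(cand$residues, function(r) {
      !identical(r, "any") && grepl(residue, r, fixed = TRUE)
    }, logical(1)), , drop = FALSE]
    if (nrow(specific) > 0) {
      cand <- specific
    } else {
      # no entry for this residue: fall back to generic terms before
      # borrowing a term specific to a different residue
      generic <- cand[cand$residues == "any", , drop = FALSE]
      if (nrow(generic) > 0) cand <- generic
    }
  }
  cand <- cand[order(abs(cand$mono_delta - delta)), , drop = FALSE]
  row_to_modification(cand[1, ])
}
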