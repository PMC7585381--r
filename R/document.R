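# The DNMSO document: root container for spectra, predictions, modifications,
# software and the CV registry. Spectra without predictions are permitted;
# predictions without spectra are not.

doc_counter <- local({
  n <- 0L
  function() {
    n <<- n + 1L
    n
  }
})

#' Create an empty DNMSO document
#'
#' @param creator Free-text creating tool/user, recorded in provenance.
#' @param created ISO-8601 creation timestamp; defaults to now (UTC).
#' @param id Document identifier; auto-generated when `NULL`.
#' @return An empty, valid `dnmso_document`.
#' @examples
#' doc <- dnmso_document(creator = "example")
#' @export
dnmso_document <- function(creator = "", created = NULL, id = NULL) {
  if (is.null(created)) {
    created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  if (is.null(id)) {
    id <- sprintf("DOC_%d_%s", doc_counter(),
                  paste(sample(c(letters, 0:9), 8, replace = TRUE), collapse = ""))
  }
  structure(
    list(
      id = id,
      provenance = list(creator = creator, created = created),
      spectra = stats::setNames(list(), character(0)),
      predictions = stats::setNames(list(), character(0)),
      modifications = stats::setNames(list(), character(0)),
      software = stats::setNames(list(), character(0)),
      cv_registry = stats::setNames(list(), character(0)),
      counters = list(spectrum = 0L, prediction = 0L),
      extra_triples = empty_triples()
    ),
    class = "dnmso_document"
  )
}

next_local_id <- function(doc, what) {
  prefix <- switch(what, spectrum = "SPEC_", prediction = "PRED_")
  pool <- switch(what, spectrum = doc$spectra, prediction = doc$predictions)
  repeat {
    doc$counters[[what]] <- doc$counters[[what]] + 1L
    id <- paste0(prefix, doc$counters[[what]])
    if (is.null(pool[[id]])) break
  }
  list(doc = doc, id = id)
}

#' Add a spectrum to a document
#'
#' Enforces the spectrum invariants at insertion time (sorted positive peaks
#' or an external reference; unique local id). Orphan spectra — spectra never
#' referenced by a prediction — are explicitly permitted.
#'
#' @param doc A [dnmso_document()].
#' @param s A [spectrum()]. When its `id` is `NULL` an id `"SPEC_n"` is
#'   assigned from a per-document counter.
#' @return The updated document (pipe-friendly); the assigned id is available
#'   as `attr(doc, "last_id")`.
#' @export
add_spectrum <- function(doc, s) {
  stopifnot(inherits(doc, "dnmso_document"), inherits(s, "dnmso_spectrum"))
  if (is.null(s$id)) {
    nx <- next_local_id(doc, "spectrum")
    doc <- nx$doc
    s$id <- nx$id
  }
  if (!is.null(doc$spectra[[s$id]])) {
    stop("identity-conflict error: spectrum id '", s$id, "' already present",
         call. = FALSE)
  }
  doc$spectra[[s$id]] <- s
  attr(doc, "last_id") <- s$id
  doc
}

#' Add a prediction to a document
#'
#' Guarded insertion: the prediction must carry at least one score and at
#' least one source spectrum reference, and every reference must resolve to a
#' spectrum already in the document (which may itself be external-ref-only).
#'
#' @param doc A [dnmso_document()].
#' @param p A [prediction()].
#' @return The updated document; assigned id in `attr(doc, "last_id")`.
#' @export
add_prediction <- function(doc, p) {
  stopifnot(inherits(doc, "dnmso_document"), inherits(p, "dnmso_prediction"))
  missing_refs <- setdiff(p$source_spectrum_refs, names(doc$spectra))
  if (length(missing_refs) > 0) {
    stop("unresolved-reference error: unknown spectrum id(s): ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  }
  for (el in p$sequence$elements) {
    if (el$kind == "mod_aa" && is.null(doc$modifications[[el$modification_ref]])) {
      stop("unresolved-reference error: modification '", el$modification_ref,
           "' not registered in document", call. = FALSE)
    }
  }
  if (is.null(p$id)) {
    nx <- next_local_id(doc, "prediction")
    doc <- nx$doc
    p$id <- nx$id
  }
  if (!is.null(doc$predictions[[p$id]])) {
    stop("identity-conflict error: prediction id '", p$id, "' already present",
         call. = FALSE)
  }
  doc$predictions[[p$id]] <- p
  attr(doc, "last_id") <- p$id
  doc
}

#' Register document-level entries
#'
#' `add_modification()`, `add_software()` and `add_cv_source()` register a
#' modification, software entry or CV source under its local id.
#'
#' @param doc A [dnmso_document()].
#' @param m,sw,cv Object built with [modification()], [software()],
#'   [cv_source()].
#' @return The updated document.
#' @export
add_modification <- function(doc, m) {
  stopifnot(inherits(doc, "dnmso_document"), inherits(m, "dnmso_modification"))
  if (!is.null(doc$modifications[[m$local_id]])) {
    stop("identity-conflict error: modification id '", m$local_id,
         "' already present", call. = FALSE)
  }
  doc$modifications[[m$local_id]] <- m
  doc
}

#' @rdname add_modification
#' @export
add_software <- function(doc, sw) {
  stopifnot(inherits(doc, "dnmso_document"), inherits(sw, "dnmso_software"))
  if (!is.null(doc$software[[sw$id]])) {
    stop("identity-conflict error: software id '", sw$id, "' already present",
         call. = FALSE)
  }
  doc$software[[sw$id]] <- sw
  doc
}

#' @rdname add_modification
#' @export
add_cv_source <- function(doc, cv) {
  stopifnot(inherits(doc, "dnmso_document"), inherits(cv, "dnmso_cv_source"))
  if (!is.null(doc$cv_registry[[cv$id]])) {
    stop("identity-conflict error: cv source id '", cv$id, "' already present",
         call. = FALSE)
  }
  doc$cv_registry[[cv$id]] <- cv
  doc
}

#' Predictions sourced from a given spectrum
#'
#' Navigates the many-to-many prediction–spectrum relationship from the
#' spectrum side: all and only predictions whose source references include
#' `spectrum_id`, in insertion order.
#'
#' @param doc A [dnmso_document()].
#' @param spectrum_id A spectrum id present in the document.
#' @return List of `dnmso_prediction`.
#' @export
predictions_for_spectrum <- function(doc, spectrum_id) {
  stopifnot(inherits(doc, "dnmso_document"))
  if (is.null(doc$spectra[[spectrum_id]])) {
    stop("unresolved-reference error: unknown spectrum id '", spectrum_id, "'",
         call. = FALSE)
  }
  Filter(function(p) spectrum_id %in% p$source_spectrum_refs, doc$predictions)
}

#' Is a document self-contained?
#'
#' A document is self-contained when every spectrum referenced by any
#' prediction carries inline peaks, so the file can be shared without the raw
#' data it was derived from. Orphan external-reference spectra do not break
#' self-containment: only prediction-referenced spectra count.
#'
#' @param doc A [dnmso_document()].
#' @return Logical scalar with attribute `external_refs`: a character vector
#'   of the referenced spectrum ids that would require external resolution.
#' @export
is_self_contained <- function(doc) {
  stopifnot(inherits(doc, "dnmso_document"))
  used <- unique(unlist(lapply(doc$predictions, `[[`, "source_spectrum_refs")))
  bad <- character(0)
  for (id in used) {
    s <- doc$spectra[[id]]
    if (is.null(s) || !has_inline_peaks(s)) bad <- c(bad, id)
  }
  structure(length(bad) == 0, external_refs = bad)
}

#' @export
print.dnmso_document <- function(x, ...) {
  cat(sprintf(
    "<dnmso document %s>\n  %d spectra, %d predictions, %d modifications, %d software\n  creator: %s (%s)\n",
    x$id, length(x$spectra), length(x$predictions), length(x$modifications),
    length(x$software), x$provenance$creator, x$provenance$created))
  invisible(x)
}

#' Tidy views of a document
#'
#' `tidy()` returns one row per prediction (id, rendered sequence, rank,
#' source spectra, each score spread into a `score_*` column); `glance()`
#' returns a one-row summary of the document.
#'
#' @param x A `dnmso_document`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dnmso_document <- function(x, ...) {
  if (length(x$predictions) == 0) {
    return(tibble::tibble(prediction = character(0), sequence = character(0),
                          rank = integer(0), n_spectra = integer(0),
                          source_spectra = character(0)))
  }
  rows <- purrr::map(x$predictions, function(p) {
    base <- tibble::tibble(
      prediction = p$id,
      sequence = render_sequence(p$sequence, modifications = x$modifications),
      rank = p$rank %||% NA_integer_,
      n_spectra = length(p$source_spectrum_refs),
      source_spectra = paste(p$source_spectrum_refs, collapse = ";")
    )
    for (s in p$scores) base[[paste0("score_", s$name)]] <- s$value
    base
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.dnmso_document
#' @export
glance.dnmso_document <- function(x, ...) {
  sc <- is_self_contained(x)
  tibble::tibble(
    id = x$id, n_spectra = length(x$spectra),
    n_predictions = length(x$predictions),
    n_modifications = length(x$modifications),
    n_software = length(x$software),
    self_contained = as.logical(sc),
    n_violations = nrow(validate_document(x))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
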