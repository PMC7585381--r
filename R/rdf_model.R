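# The DNMSO RDF vocabulary and the mapping between documents and triples.
# The format is ontology-based: a document is a graph. Ordered collections
# (spectra, predictions, sequence elements, scores) are encoded as RDF lists
# so that order survives round-trip exactly; inline peak lists are encoded as
# a single CSV literal per spectrum, which keeps instances small and makes
# the peak values bit-exact.

#' DNMSO vocabulary namespace IRI (versioned)
#' @export
DNMSO_NS <- "https://w3id.org/dnmso/1.0#"
DNMSO_NS_ROOT <- "https://w3id.org/dnmso/"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

d <- function(x) paste0(DNMSO_NS, x)
r <- function(x) paste0(RDF_NS, x)
x_ <- function(x) paste0(XSD_NS, x)

RDF_TYPE <- r("type")
RDF_FIRST <- r("first")
RDF_REST <- r("rest")
RDF_NIL <- r("nil")

enc_id <- function(x) utils::URLencode(x, reserved = TRUE)
dec_id <- function(x) utils::URLdecode(x)

empty_triples <- function() {
  tibble::tibble(s = character(0), p = character(0), o = character(0),
                 ot = character(0), dt = character(0))
}

# Mutable triple collector. Triples are pushed onto a cons list (head
# binding reassignment only): subscript-assigning into an environment-held
# vector from inside a function copies the whole vector on every write,
# which made naive appends quadratic. The list is materialized into column
# vectors once, in collector_to_tibble().
new_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$head <- NULL
  env$i <- 0L
  env$blank <- 0L
  env
}

emit <- function(col, s, p, o, ot = "iri", dt = NA_character_) {
  col$head <- list(c(s, p, o, ot, dt), col$head)
  col$i <- col$i + 1L
}

emit_lit <- function(col, s, p, value, dt = NA_character_) {
  emit(col, s, p, as.character(value), ot = "literal", dt = dt)
}

emit_dbl <- function(col, s, p, value) emit_lit(col, s, p, fmt_num(value), x_("double"))
emit_int <- function(col, s, p, value) emit_lit(col, s, p, as.character(as.integer(value)), x_("integer"))

fresh_blank <- function(col) {
  col$blank <- col$blank + 1L
  paste0("_:b", col$blank)
}

# Encode an ordered collection of node IRIs as an RDF list; returns the IRI
# or blank node standing for the list head.
emit_list <- function(col, items) {
  if (length(items) == 0) return(RDF_NIL)
  head <- fresh_blank(col)
  cell <- head
  for (k in seq_along(items)) {
    emit(col, cell, RDF_FIRST, items[[k]], ot = "iri")
    nxt <- if (k < length(items)) fresh_blank(col) else RDF_NIL
    emit(col, cell, RDF_REST, nxt, ot = "iri")
    cell <- nxt
  }
  head
}

collector_to_tibble <- function(col) {
  n <- col$i
  if (n == 0L) return(empty_triples())
  s <- character(n); p <- character(n); o <- character(n)
  ot <- character(n); dt <- character(n)
  h <- col$head
  for (k in n:1) {
    v <- h[[1]]
    s[k] <- v[1]; p[k] <- v[2]; o[k] <- v[3]; ot[k] <- v[4]; dt[k] <- v[5]
    h <- h[[2]]
  }
  tibble::tibble(s = s, p = p, o = o, ot = ot, dt = dt)
}

doc_iri <- function(doc_id) paste0("urn:dnmso:", enc_id(doc_id))
node_iri <- function(doc_id, kind, id) {
  paste0(doc_iri(doc_id), "/", kind, "/", enc_id(id))
}

encode_supporting_peaks <- function(sp) {
  paste(paste0(enc_id(sp$spectrum_id), ":", sp$peak_index), collapse = " ")
}

decode_supporting_peaks <- function(txt) {
  if (!nzchar(txt)) return(NULL)
  parts <- strsplit(strsplit(txt, " ", fixed = TRUE)[[1]], ":(?=[0-9]+$)", perl = TRUE)
  tibble::tibble(
    spectrum_id = vapply(parts, function(p) dec_id(p[1]), character(1)),
    peak_index = vapply(parts, function(p) as.integer(p[2]), integer(1))
  )
}

#' Convert a document to its RDF triple table
#'
#' The canonical graph view of a document: a tibble with columns `s`, `p`,
#' `o`, `ot` (`"iri"` or `"literal"`; blank nodes are `_:`-prefixed terms),
#' `dt` (datatype IRI or `NA`). Emission order is deterministic, so all
#' serializations of the same document are byte-identical.
#'
#' @param doc A `dnmso_document`.
#' @return A triple tibble.
#' @export
document_to_triples <- function(doc) {
  stopifnot(inherits(doc, "dnmso_document"))
  col <- new_collector()
  di <- doc_iri(doc$id)
  emit(col, di, RDF_TYPE, d("Document"))
  emit_lit(col, di, d("localId"), doc$id)
  emit_lit(col, di, d("creator"), doc$provenance$creator %||% "")
  emit_lit(col, di, d("created"), doc$provenance$created %||% "")

  cv_iris <- vapply(names(doc$cv_registry), function(id) node_iri(doc$id, "cv", id), character(1))
  emit(col, di, d("cvSources"), emit_list(col, cv_iris))
  mod_iris <- vapply(names(doc$modifications), function(id) node_iri(doc$id, "modification", id), character(1))
  emit(col, di, d("modifications"), emit_list(col, mod_iris))
  sw_iris <- vapply(names(doc$software), function(id) node_iri(doc$id, "software", id), character(1))
  emit(col, di, d("software"), emit_list(col, sw_iris))
  spec_iris <- vapply(names(doc$spectra), function(id) node_iri(doc$id, "spectrum", id), character(1))
  emit(col, di, d("spectra"), emit_list(col, spec_iris))
  pred_iris <- vapply(names(doc$predictions), function(id) node_iri(doc$id, "prediction", id), character(1))
  emit(col, di, d("predictions"), emit_list(col, pred_iris))

  for (k in seq_along(doc$cv_registry)) {
    cv <- doc$cv_registry[[k]]
    ni <- cv_iris[[k]]
    emit(col, ni, RDF_TYPE, d("CVSource"))
    emit_lit(col, ni, d("localId"), cv$id)
    emit_lit(col, ni, d("fullName"), cv$full_name)
    emit_lit(col, ni, d("version"), cv$version)
    emit_lit(col, ni, d("uri"), cv$uri)
  }
  for (k in seq_along(doc$modifications)) {
    m <- doc$modifications[[k]]
    ni <- mod_iris[[k]]
    emit(col, ni, RDF_TYPE, d("Modification"))
    emit_lit(col, ni, d("localId"), m$local_id)
    emit_lit(col, ni, d("psimodAccession"), m$psimod_accession)
    emit_lit(col, ni, d("modName"), m$name)
    emit_dbl(col, ni, d("monoMassDelta"), m$mono_mass_delta)
    if (!is.na(m$avg_mass_delta)) emit_dbl(col, ni, d("avgMassDelta"), m$avg_mass_delta)
    emit_lit(col, ni, d("residueSpecificity"), paste(m$residue_specificity, collapse = ""))
    emit_lit(col, ni, d("terminus"), m$terminus)
  }
  for (k in seq_along(doc$software)) {
    sw <- doc$software[[k]]
    ni <- sw_iris[[k]]
    emit(col, ni, RDF_TYPE, d("Software"))
    emit_lit(col, ni, d("localId"), sw$id)
    emit_lit(col, ni, d("swName"), sw$name)
    emit_lit(col, ni, d("swVersion"), sw$version)
    if (length(sw$parameters) > 0) {
      par_iris <- vapply(seq_along(sw$parameters), function(j) paste0(ni, "/param/", j), character(1))
      emit(col, ni, d("parameters"), emit_list(col, par_iris))
      for (j in seq_along(sw$parameters)) {
        pp <- sw$parameters[[j]]
        pi <- par_iris[[j]]
        if (inherits(pp, "dnmso_cv_param")) {
          emit(col, pi, RDF_TYPE, d("CVParam"))
          emit_lit(col, pi, d("cvRef"), pp$cv_ref)
          emit_lit(col, pi, d("cvAccession"), pp$accession)
          emit_lit(col, pi, d("paramName"), pp$name)
          if (!is.null(pp$value)) emit_lit(col, pi, d("paramValue"), pp$value)
        } else {
          emit(col, pi, RDF_TYPE, d("UserParam"))
          emit_lit(col, pi, d("paramName"), names(sw$parameters)[j] %||% "")
          emit_lit(col, pi, d("paramValue"), as.character(pp))
        }
      }
    }
  }
  for (k in seq_along(doc$spectra)) {
    s <- doc$spectra[[k]]
    ni <- spec_iris[[k]]
    emit(col, ni, RDF_TYPE, d("Spectrum"))
    emit_lit(col, ni, d("localId"), s$id)
    if (!is.na(s$precursor_mz)) emit_dbl(col, ni, d("precursorMz"), s$precursor_mz)
    if (!is.na(s$precursor_charge)) emit_int(col, ni, d("precursorCharge"), s$precursor_charge)
    if (!is.null(s$native_id)) emit_lit(col, ni, d("nativeId"), s$native_id)
    if (!is.null(s$retention_time_s)) emit_dbl(col, ni, d("retentionTime"), s$retention_time_s)
    if (!is.null(s$fragmentation)) emit_lit(col, ni, d("fragmentation"), s$fragmentation)
    if (has_inline_peaks(s)) emit_lit(col, ni, d("peaksCsv"), peaks_to_csv_body(s$peaks))
    if (!is.null(s$external_ref)) {
      ei <- paste0(ni, "/extref")
      emit(col, ni, d("externalRef"), ei)
      emit(col, ei, RDF_TYPE, d("ExternalSpectrumRef"))
      emit_lit(col, ei, d("filePath"), s$external_ref$file_path_or_uri)
      emit_lit(col, ei, d("formatHint"), s$external_ref$format_hint)
      emit_lit(col, ei, d("nativeId"), s$external_ref$native_id)
    }
  }
  for (k in seq_along(doc$predictions)) {
    p <- doc$predictions[[k]]
    ni <- pred_iris[[k]]
    emit(col, ni, RDF_TYPE, d("Prediction"))
    emit_lit(col, ni, d("localId"), p$id)
    if (!is.null(p$rank)) emit_int(col, ni, d("rank"), p$rank)
    if (!is.null(p$software_ref)) emit_lit(col, ni, d("softwareRef"), p$software_ref)
    src_iris <- vapply(p$source_spectrum_refs, function(id) node_iri(doc$id, "spectrum", id), character(1))
    emit(col, ni, d("sourceSpectra"), emit_list(col, src_iris))
    sc_iris <- vapply(seq_along(p$scores), function(j) paste0(ni, "/score/", j), character(1))
    emit(col, ni, d("scores"), emit_list(col, sc_iris))
    for (j in seq_along(p$scores)) {
      sc <- p$scores[[j]]
      si <- sc_iris[[j]]
      emit(col, si, RDF_TYPE, d("Score"))
      emit_lit(col, si, d("scoreName"), sc$name)
      emit_dbl(col, si, d("scoreValue"), sc$value)
      if (!is.null(sc$cv_accession)) emit_lit(col, si, d("cvAccession"), sc$cv_accession)
    }
    qi <- paste0(ni, "/seq")
    emit(col, ni, d("sequence"), qi)
    emit(col, qi, RDF_TYPE, d("Sequence"))
    el_iris <- vapply(seq_len(seq_length(p$sequence)), function(j) paste0(qi, "/el/", j), character(1))
    emit(col, qi, d("elements"), emit_list(col, el_iris))
    for (j in seq_len(seq_length(p$sequence))) {
      el <- p$sequence$elements[[j]]
      ei <- el_iris[[j]]
      emit(col, ei, RDF_TYPE, d(switch(el$kind, aa = "AminoAcid",
                                       mod_aa = "ModifiedAminoAcid", gap = "Gap")))
      if (!is.null(el$residue)) emit_lit(col, ei, d("residue"), el$residue)
      if (!is.null(el$modification_ref)) emit_lit(col, ei, d("modificationRef"), el$modification_ref)
      if (!is.null(el$mass)) emit_dbl(col, ei, d("gapMass"), el$mass)
      if (!is.null(el$confidence)) emit_dbl(col, ei, d("confidence"), el$confidence)
      if (!is.null(el$supporting_peaks) && nrow(el$supporting_peaks) > 0) {
        emit_lit(col, ei, d("supportingPeaks"), encode_supporting_peaks(el$supporting_peaks))
      }
    }
  }
  out <- collector_to_tibble(col)
  if (nrow(doc$extra_triples) > 0) {
    extras <- doc$extra_triples[order(doc$extra_triples$s, doc$extra_triples$p,
                                      doc$extra_triples$o), , drop = FALSE]
    out <- dplyr::bind_rows(out, extras)
  }
  out
}

# ---- triples -> document --------------------------------------------------

# Index-backed view of a triple table with consumption tracking; triples not
# consumed while rebuilding the document are foreign and kept opaquely.
new_graph_view <- function(tr) {
  key <- paste0(tr$s, "\r", tr$p)
  env <- new.env(parent = emptyenv())
  env$tr <- tr
  env$index <- list2env(split(seq_len(nrow(tr)), key), hash = TRUE,
                        envir = new.env(parent = emptyenv()))
  env$used_head <- NULL
  env
}

gv_rows <- function(gv, s, p, consume = TRUE) {
  idx <- gv$index[[paste0(s, "\r", p)]]
  if (is.null(idx)) return(integer(0))
  if (consume) gv$used_head <- list(idx, gv$used_head)
  idx
}

gv_unused <- function(gv) {
  used <- rep(FALSE, nrow(gv$tr))
  h <- gv$used_head
  while (!is.null(h)) {
    used[h[[1]]] <- TRUE
    h <- h[[2]]
  }
  gv$tr[!used, , drop = FALSE]
}

gv_obj1 <- function(gv, s, p) {
  idx <- gv_rows(gv, s, p)
  if (length(idx) == 0) return(NULL)
  gv$tr$o[idx[1]]
}

gv_num1 <- function(gv, s, p) {
  v <- gv_obj1(gv, s, p)
  if (is.null(v)) NULL else as.numeric(v)
}

gv_list <- function(gv, head) {
  items <- character(0)
  while (!identical(head, RDF_NIL)) {
    first <- gv_obj1(gv, head, RDF_FIRST)
    nxt <- gv_obj1(gv, head, RDF_REST)
    if (is.null(first) || is.null(nxt)) break  # malformed list: stop walking
    items <- c(items, first)
    head <- nxt
  }
  items
}

#' Rebuild a document from its RDF triple table
#'
#' Inverse of [document_to_triples()]. Cardinality violations (e.g. a
#' prediction without a spectrum link) are loaded as-is and surfaced by
#' [validate_document()], not rejected here. Triples in foreign namespaces
#' are preserved opaquely in `doc$extra_triples` and re-emitted on
#' serialization.
#'
#' @param tr A triple tibble.
#' @return A `dnmso_document`.
#' @export
triples_to_document <- function(tr) {
  doc_rows <- tr$s[tr$p == RDF_TYPE & tr$o == d("Document")]
  if (length(doc_rows) == 0) {
    other <- grepl(paste0("^", DNMSO_NS_ROOT), tr$p) | grepl(paste0("^", DNMSO_NS_ROOT), tr$o)
    versions <- unique(sub("#.*$", "", grep(paste0("^", DNMSO_NS_ROOT),
                                            c(tr$p, tr$o), value = TRUE)))
    versions <- setdiff(versions, sub("#$", "", DNMSO_NS))
    if (any(other) && length(versions) > 0) {
      stop("version error: graph uses unknown DNMSO namespace version(s): ",
           paste(versions, collapse = ", "), call. = FALSE)
    }
    stop("version error: no DNMSO Document node in graph", call. = FALSE)
  }
  gv <- new_graph_view(tr)
  di <- doc_rows[1]
  gv_rows(gv, di, RDF_TYPE)

  doc <- dnmso_document(creator = gv_obj1(gv, di, d("creator")) %||% "",
                        created = gv_obj1(gv, di, d("created")) %||% "",
                        id = gv_obj1(gv, di, d("localId")) %||% "doc")
  doc$extra_triples <- empty_triples()

  for (ni in gv_list(gv, gv_obj1(gv, di, d("cvSources")) %||% RDF_NIL)) {
    gv_rows(gv, ni, RDF_TYPE)
    cv <- cv_source(id = gv_obj1(gv, ni, d("localId")) %||% ni,
                    full_name = gv_obj1(gv, ni, d("fullName")) %||% "",
                    version = gv_obj1(gv, ni, d("version")) %||% "",
                    uri = gv_obj1(gv, ni, d("uri")) %||% "")
    doc$cv_registry[[cv$id]] <- cv
  }
  for (ni in gv_list(gv, gv_obj1(gv, di, d("modifications")) %||% RDF_NIL)) {
    gv_rows(gv, ni, RDF_TYPE)
    res <- gv_obj1(gv, ni, d("residueSpecificity")) %||% "any"
    m <- structure(list(
      local_id = gv_obj1(gv, ni, d("localId")) %||% ni,
      psimod_accession = gv_obj1(gv, ni, d("psimodAccession")),
      name = gv_obj1(gv, ni, d("modName")) %||% "",
      mono_mass_delta = gv_num1(gv, ni, d("monoMassDelta")) %||% NA_real_,
      avg_mass_delta = gv_num1(gv, ni, d("avgMassDelta")) %||% NA_real_,
      residue_specificity = if (identical(res, "any")) "any" else strsplit(res, "")[[1]],
      terminus = gv_obj1(gv, ni, d("terminus")) %||% "none"
    ), class = "dnmso_modification")
    doc$modifications[[m$local_id]] <- m
  }
  for (ni in gv_list(gv, gv_obj1(gv, di, d("software")) %||% RDF_NIL)) {
    gv_rows(gv, ni, RDF_TYPE)
    params <- list()
    pnames <- character(0)
    for (pi in gv_list(gv, gv_obj1(gv, ni, d("parameters")) %||% RDF_NIL)) {
      ptype <- gv_obj1(gv, pi, RDF_TYPE)
      if (identical(ptype, d("CVParam"))) {
        params[[length(params) + 1L]] <- cv_param(
          cv_ref = gv_obj1(gv, pi, d("cvRef")) %||% "",
          accession = gv_obj1(gv, pi, d("cvAccession")) %||% "XX:0",
          name = gv_obj1(gv, pi, d("paramName")) %||% "",
          value = gv_obj1(gv, pi, d("paramValue")))
        pnames <- c(pnames, "")
      } else {
        params[[length(params) + 1L]] <- gv_obj1(gv, pi, d("paramValue")) %||% ""
        pnames <- c(pnames, gv_obj1(gv, pi, d("paramName")) %||% "")
      }
    }
    names(params) <- pnames
    sw <- software(name = gv_obj1(gv, ni, d("swName")) %||% "?",
                   version = gv_obj1(gv, ni, d("swVersion")) %||% "",
                   parameters = params,
                   id = gv_obj1(gv, ni, d("localId")) %||% ni)
    doc$software[[sw$id]] <- sw
  }
  for (ni in gv_list(gv, gv_obj1(gv, di, d("spectra")) %||% RDF_NIL)) {
    gv_rows(gv, ni, RDF_TYPE)
    ext <- NULL
    ei <- gv_obj1(gv, ni, d("externalRef"))
    if (!is.null(ei)) {
      gv_rows(gv, ei, RDF_TYPE)
      ext <- structure(list(
        file_path_or_uri = gv_obj1(gv, ei, d("filePath")) %||% "",
        format_hint = gv_obj1(gv, ei, d("formatHint")) %||% "other",
        native_id = gv_obj1(gv, ei, d("nativeId")) %||% ""
      ), class = "dnmso_external_ref")
    }
    csv <- gv_obj1(gv, ni, d("peaksCsv"))
    peaks <- if (is.null(csv)) empty_peaks() else csv_body_to_peaks(csv)
    charge <- gv_obj1(gv, ni, d("precursorCharge"))
    s <- structure(list(
      id = gv_obj1(gv, ni, d("localId")) %||% ni,
      precursor_mz = gv_num1(gv, ni, d("precursorMz")) %||% NA_real_,
      precursor_charge = if (is.null(charge)) NA_integer_ else as.integer(charge),
      peaks = peaks, external_ref = ext,
      native_id = gv_obj1(gv, ni, d("nativeId")),
      retention_time_s = gv_num1(gv, ni, d("retentionTime")),
      fragmentation = gv_obj1(gv, ni, d("fragmentation"))
    ), class = "dnmso_spectrum")
    doc$spectra[[s$id]] <- s
  }
  for (ni in gv_list(gv, gv_obj1(gv, di, d("predictions")) %||% RDF_NIL)) {
    gv_rows(gv, ni, RDF_TYPE)
    src <- unname(vapply(gv_list(gv, gv_obj1(gv, ni, d("sourceSpectra")) %||% RDF_NIL),
                  function(iri) {
                    id <- gv_obj1(gv, iri, d("localId"))
                    if (!is.null(id)) return(id)
                    dec_id(sub(".*/spectrum/", "", iri))
                  }, character(1)))
    scores <- list()
    for (si in gv_list(gv, gv_obj1(gv, ni, d("scores")) %||% RDF_NIL)) {
      gv_rows(gv, si, RDF_TYPE)
      scores[[length(scores) + 1L]] <- score(
        name = gv_obj1(gv, si, d("scoreName")) %||% "score",
        value = gv_num1(gv, si, d("scoreValue")) %||% NA_real_,
        cv_accession = gv_obj1(gv, si, d("cvAccession")))
    }
    qi <- gv_obj1(gv, ni, d("sequence"))
    els <- list()
    if (!is.null(qi)) {
      gv_rows(gv, qi, RDF_TYPE)
      for (ei in gv_list(gv, gv_obj1(gv, qi, d("elements")) %||% RDF_NIL)) {
        etype <- gv_obj1(gv, ei, RDF_TYPE) %||% d("AminoAcid")
        kind <- switch(sub(paste0("^", DNMSO_NS), "", etype),
                       AminoAcid = "aa", ModifiedAminoAcid = "mod_aa",
                       Gap = "gap", "aa")
        sp <- gv_obj1(gv, ei, d("supportingPeaks"))
        els[[length(els) + 1L]] <- structure(list(
          kind = kind,
          residue = gv_obj1(gv, ei, d("residue")),
          modification_ref = gv_obj1(gv, ei, d("modificationRef")),
          mass = gv_num1(gv, ei, d("gapMass")),
          confidence = gv_num1(gv, ei, d("confidence")),
          supporting_peaks = if (is.null(sp)) NULL else decode_supporting_peaks(sp)
        ), class = c(paste0("dnmso_", kind), "dnmso_element"))
      }
    }
    rank <- gv_obj1(gv, ni, d("rank"))
    p <- structure(list(
      id = gv_obj1(gv, ni, d("localId")) %||% ni,
      sequence = structure(list(elements = els), class = "dnmso_sequence"),
      scores = scores,
      source_spectrum_refs = src,
      software_ref = gv_obj1(gv, ni, d("softwareRef")),
      rank = if (is.null(rank)) NULL else as.integer(rank)
    ), class = "dnmso_prediction")
    doc$predictions[[p$id]] <- p
  }

  doc$extra_triples <- gv_unused(gv)
  doc
}
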