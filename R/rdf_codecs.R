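# RDF serialization dialects: Turtle (default), RDF/XML and JSON-LD, all
# writing the same deterministic triple stream. Writers emit byte-identical
# output for a fixed document; readers rebuild the triple table, from which
# triples_to_document() reconstructs the document.

prefix_map <- function() c(dnmso = DNMSO_NS, rdf = RDF_NS, xsd = XSD_NS)

compact_iri <- function(iri) {
  pm <- prefix_map()
  out <- iri
  for (pfx in names(pm)) {
    hit <- startsWith(iri, pm[[pfx]])
    out[hit] <- paste0(pfx, ":", substring(iri[hit], nchar(pm[[pfx]]) + 1L))
  }
  out
}

expand_prefixed <- function(term, pm = prefix_map()) {
  m <- regmatches(term, regexpr("^([A-Za-z][A-Za-z0-9_.-]*):", term))
  if (length(m) == 0) return(term)
  pfx <- sub(":$", "", m)
  if (!pfx %in% names(pm)) return(term)
  paste0(pm[[pfx]], substring(term, nchar(m) + 1L))
}

escape_ttl <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_ttl <- function(x) {
  vapply(x, function(s) {
    s <- gsub("\\t", "\t", s, fixed = TRUE)
    s <- gsub("\\r", "\r", s, fixed = TRUE)
    s <- gsub("\\n", "\n", s, fixed = TRUE)
    s <- gsub('\\"', '"', s, fixed = TRUE)
    gsub("\\\\", "\\", s, fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

ttl_iri_term <- function(iri) {
  # prefixed names only for our clean vocab locals; everything else gets <>
  ok <- startsWith(iri, DNMSO_NS) | startsWith(iri, RDF_NS) | startsWith(iri, XSD_NS)
  ifelse(ok, compact_iri(iri), paste0("<", iri, ">"))
}

ttl_term <- function(o, ot, dt) {
  is_blank <- startsWith(o, "_:")
  is_lit <- ot == "literal"
  out <- character(length(o))
  out[is_blank] <- o[is_blank]
  idx <- !is_blank & !is_lit
  out[idx] <- ttl_iri_term(o[idx])
  if (any(is_lit)) {
    lex <- paste0('"', escape_ttl(o[is_lit]), '"')
    dts <- dt[is_lit]
    typed <- !is.na(dts)
    lex[typed] <- paste0(lex[typed], "^^", ttl_iri_term(dts[typed]))
    out[is_lit] <- lex
  }
  out
}

triples_to_turtle <- function(tr) {
  header <- c(sprintf("@prefix dnmso: <%s> .", DNMSO_NS),
              sprintf("@prefix rdf: <%s> .", RDF_NS),
              sprintf("@prefix xsd: <%s> .", XSD_NS), "")
  if (nrow(tr) == 0) return(paste0(paste(header, collapse = "\n"), "\n"))
  s <- ifelse(startsWith(tr$s, "_:"), tr$s, ttl_iri_term(tr$s))
  p <- ttl_iri_term(tr$p)
  o <- ttl_term(tr$o, tr$ot, tr$dt)
  paste0(paste(c(header, paste(s, p, o, ".")), collapse = "\n"), "\n")
}

# -- Turtle reading: a vectorized fast path for the line-oriented form this
#    package writes, plus a general tokenizing parser for hand-written files
#    (prefix declarations, ';'/',' continuations, collections, '[]').

turtle_to_triples <- function(text) {
  fast <- try_fast_turtle(text)
  if (!is.null(fast)) return(fast)
  general_turtle_parse(text)
}

try_fast_turtle <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pfx_lines <- grepl("^@prefix ", lines)
  pm <- prefix_map()
  for (pl in lines[pfx_lines]) {
    m <- regmatches(pl, regexec("^@prefix ([A-Za-z][A-Za-z0-9_.-]*): <([^>]*)> \\.$", pl))[[1]]
    if (length(m) == 0) return(NULL)
    pm[m[2]] <- m[3]
  }
  body <- lines[!pfx_lines]
  if (length(body) == 0) return(empty_triples())
  m <- stringr::str_match(body, "^(\\S+) (\\S+) (.*) \\.$")
  if (anyNA(m[, 1])) return(NULL)
  s <- resolve_fast_term(m[, 2], pm)
  p <- resolve_fast_term(m[, 3], pm)
  if (anyNA(s) || anyNA(p)) return(NULL)
  oraw <- m[, 4]
  lit <- startsWith(oraw, '"')
  o <- character(length(oraw)); ot <- character(length(oraw)); dt <- rep(NA_character_, length(oraw))
  if (any(lit)) {
    lm <- stringr::str_match(oraw[lit], '^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(\\S+))?$')
    if (anyNA(lm[, 1])) return(NULL)
    o[lit] <- unescape_ttl(lm[, 2])
    ot[lit] <- "literal"
    has_dt <- !is.na(lm[, 3])
    dt[lit][has_dt] <- resolve_fast_term(lm[has_dt, 3], pm)
  }
  res <- resolve_fast_term(oraw[!lit], pm)
  if (anyNA(res)) return(NULL)
  o[!lit] <- res
  ot[!lit] <- "iri"
  tibble::tibble(s = s, p = p, o = o, ot = ot, dt = dt)
}

resolve_fast_term <- function(x, pm) {
  out <- rep(NA_character_, length(x))
  if (length(x) == 0) return(out)
  iri <- grepl("^<[^>]*>$", x)
  out[iri] <- substr(x[iri], 2, nchar(x[iri]) - 1L)
  blank <- startsWith(x, "_:")
  out[blank] <- x[blank]
  out[x == "a"] <- RDF_TYPE
  pn <- is.na(out) & grepl("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*$", x)
  if (any(pn)) {
    pfx <- sub(":.*$", "", x[pn])
    local <- sub("^[^:]*:", "", x[pn])
    known <- pfx %in% names(pm)
    vals <- rep(NA_character_, sum(pn))
    vals[known] <- paste0(pm[pfx[known]], local[known])
    out[pn] <- vals
  }
  out
}

TTL_TOKEN_RE <- paste0(
  '@prefix|@base',
  '|<[^>]*>',
  '|"(?:[^"\\\\]|\\\\.)*"',
  '|_:[A-Za-z0-9_]+',
  '|\\^\\^',
  '|@[a-zA-Z][a-zA-Z-]*',
  '|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*',
  '|[A-Za-z][A-Za-z0-9_.-]*:',
  '|:',
  '|[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?',
  '|\\ba\\b|true|false',
  '|[.;,()\\[\\]]'
)

# Strip '#' comments outside quoted literals and <> IRIs, line by line.
strip_ttl_comments <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- vapply(lines, function(line) {
    if (!grepl("#", line, fixed = TRUE)) return(line)
    chars <- strsplit(line, "")[[1]]
    in_q <- FALSE; in_iri <- FALSE; esc <- FALSE
    for (k in seq_along(chars)) {
      ch <- chars[k]
      if (esc) { esc <- FALSE; next }
      if (in_q) {
        if (ch == "\\") esc <- TRUE else if (ch == '"') in_q <- FALSE
      } else if (in_iri) {
        if (ch == ">") in_iri <- FALSE
      } else if (ch == '"') in_q <- TRUE
      else if (ch == "<") in_iri <- TRUE
      else if (ch == "#") return(substr(line, 1, k - 1L))
    }
    line
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "\n")
}

general_turtle_parse <- function(text) {
  text <- strip_ttl_comments(text)
  toks <- regmatches(text, gregexpr(TTL_TOKEN_RE, text, perl = TRUE))[[1]]
  pm <- prefix_map()
  col <- new_collector()
  col$blank <- 100000L # keep parser-generated labels clear of document ones
  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[i] else ""
  nexttok <- function() {
    if (i > n) stop("query/parse error: unexpected end of Turtle input", call. = FALSE)
    t <- toks[i]; i <<- i + 1L; t
  }
  expect <- function(t) {
    got <- nexttok()
    if (got != t) stop("parse error near token ", i - 1L, ": expected '", t,
                       "' got '", got, "'", call. = FALSE)
  }
  term <- function(as_object = FALSE) {
    t <- nexttok()
    if (t == "a") return(list(v = RDF_TYPE, ot = "iri", dt = NA))
    if (startsWith(t, "<")) return(list(v = substr(t, 2, nchar(t) - 1L), ot = "iri", dt = NA))
    if (startsWith(t, "_:")) return(list(v = t, ot = "iri", dt = NA))
    if (startsWith(t, '"')) {
      v <- unescape_ttl(substr(t, 2, nchar(t) - 1L))
      dt <- NA_character_
      if (peek() == "^^") { nexttok(); dtt <- term(); dt <- dtt$v }
      else if (startsWith(peek(), "@")) nexttok() # drop language tag
      return(list(v = v, ot = "literal", dt = dt))
    }
    if (grepl("^[+-]?[0-9]", t)) {
      dt <- if (grepl("[.eE]", t)) x_("double") else x_("integer")
      return(list(v = t, ot = "literal", dt = dt))
    }
    if (t %in% c("true", "false")) return(list(v = t, ot = "literal", dt = x_("boolean")))
    if (t == "(") {
      items <- list()
      while (peek() != ")") items[[length(items) + 1L]] <- term(TRUE)
      nexttok()
      if (length(items) == 0) return(list(v = RDF_NIL, ot = "iri", dt = NA))
      head <- fresh_blank(col)
      cell <- head
      for (k in seq_along(items)) {
        it <- items[[k]]
        emit(col, cell, RDF_FIRST, it$v, ot = it$ot, dt = it$dt %||% NA_character_)
        nxt <- if (k < length(items)) fresh_blank(col) else RDF_NIL
        emit(col, cell, RDF_REST, nxt)
        cell <- nxt
      }
      return(list(v = head, ot = "iri", dt = NA))
    }
    if (t == "[") {
      b <- fresh_blank(col)
      if (peek() != "]") pred_obj_list(b)
      expect("]")
      return(list(v = b, ot = "iri", dt = NA))
    }
    if (grepl(":", t, fixed = TRUE)) {
      ex <- expand_prefixed(t, pm)
      if (identical(ex, t) && !grepl("^[a-z]+://", t) && !startsWith(t, "urn:")) {
        stop("parse error near token ", i - 1L, ": undefined prefix in '", t, "'",
             call. = FALSE)
      }
      return(list(v = ex, ot = "iri", dt = NA))
    }
    stop("parse error near token ", i - 1L, ": unexpected '", t, "'", call. = FALSE)
  }
  pred_obj_list <- function(subj) {
    repeat {
      v <- term()
      repeat {
        obj <- term(TRUE)
        emit(col, subj, v$v, obj$v, ot = obj$ot, dt = obj$dt %||% NA_character_)
        if (peek() == ",") nexttok() else break
      }
      if (peek() == ";") {
        nexttok()
        if (peek() %in% c(".", "]", "")) break
      } else break
    }
  }
  while (i <= n) {
    if (peek() %in% c("@prefix", "@base")) {
      kw <- nexttok()
      if (kw == "@prefix") {
        pdecl <- nexttok() # "pfx:" or ":"
        iri <- nexttok()
        pm[sub(":$", "", pdecl)] <- substr(iri, 2, nchar(iri) - 1L)
        expect(".")
      } else {
        nexttok(); expect(".")
      }
      next
    }
    subj <- term()
    pred_obj_list(subj$v)
    expect(".")
  }
  collector_to_tibble(col)
}

# ---- RDF/XML --------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

split_iri <- function(iri) {
  cut <- regexpr("[#/]([^#/]+)$", iri, perl = TRUE)
  if (cut < 0) return(c(ns = "", local = iri))
  c(ns = substr(iri, 1, cut), local = substr(iri, cut + 1L, nchar(iri)))
}

triples_to_rdfxml <- function(tr) {
  # assign prefixes: dnmso, rdf, then ns1.. for foreign predicate namespaces
  preds <- unique(tr$p)
  parts <- t(vapply(preds, split_iri, character(2)))
  ns_known <- c(DNMSO_NS, RDF_NS)
  foreign <- unique(parts[, "ns"][!parts[, "ns"] %in% ns_known])
  foreign <- foreign[nzchar(foreign)]
  nsmap <- stats::setNames(c(DNMSO_NS, RDF_NS), c("dnmso", "rdf"))
  if (length(foreign) > 0) {
    nsmap <- c(nsmap, stats::setNames(foreign, paste0("ns", seq_along(foreign))))
  }
  qname <- function(iri) {
    sp <- split_iri(iri)
    pfx <- names(nsmap)[match(sp[["ns"]], nsmap)]
    if (is.na(pfx)) stop("cannot form a QName for predicate <", iri, ">", call. = FALSE)
    paste0(pfx, ":", sp[["local"]])
  }
  subjects <- unique(tr$s)
  rows_by_subject <- split(seq_len(nrow(tr)), factor(tr$s, levels = subjects))
  blocks <- vapply(seq_along(subjects), function(si) {
    su <- subjects[si]
    rows <- rows_by_subject[[si]]
    about <- if (startsWith(su, "_:")) sprintf(' rdf:nodeID="%s"', substring(su, 3))
             else sprintf(' rdf:about="%s"', xml_escape(su))
    props <- vapply(rows, function(k) {
      qn <- qname(tr$p[k])
      if (tr$ot[k] == "literal") {
        dt <- if (!is.na(tr$dt[k])) sprintf(' rdf:datatype="%s"', tr$dt[k]) else ""
        sprintf("    <%s%s>%s</%s>", qn, dt, xml_escape(tr$o[k]), qn)
      } else if (startsWith(tr$o[k], "_:")) {
        sprintf('    <%s rdf:nodeID="%s"/>', qn, substring(tr$o[k], 3))
      } else {
        sprintf('    <%s rdf:resource="%s"/>', qn, xml_escape(tr$o[k]))
      }
    }, character(1))
    paste0("  <rdf:Description", about, ">\n", paste(props, collapse = "\n"),
           "\n  </rdf:Description>")
  }, character(1))
  ns_decls <- paste(sprintf('xmlns:%s="%s"', names(nsmap), nsmap), collapse = " ")
  paste0('<?xml version="1.0" encoding="utf-8"?>\n<rdf:RDF ', ns_decls, ">\n",
         paste(blocks, collapse = "\n"), "\n</rdf:RDF>\n")
}

rdfxml_to_triples <- function(text) {
  xml <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("parse error: malformed RDF/XML: ",
                                           conditionMessage(e), call. = FALSE))
  nsmap <- xml2::xml_ns(xml)
  col <- new_collector()
  for (desc in xml2::xml_children(xml)) {
    about <- xml2::xml_attr(desc, "about")
    nid <- xml2::xml_attr(desc, "nodeID")
    su <- if (!is.na(about)) about else paste0("_:", nid)
    for (child in xml2::xml_children(desc)) {
      qn <- xml2::xml_name(child, ns = nsmap)
      pfx <- sub(":.*$", "", qn)
      local <- sub("^[^:]*:", "", qn)
      ns <- as.character(nsmap[pfx])
      p <- paste0(ns, local)
      res <- xml2::xml_attr(child, "resource")
      onid <- xml2::xml_attr(child, "nodeID")
      if (!is.na(res)) {
        emit(col, su, p, res, ot = "iri")
      } else if (!is.na(onid)) {
        emit(col, su, p, paste0("_:", onid), ot = "iri")
      } else {
        dt <- xml2::xml_attr(child, "datatype")
        emit(col, su, p, xml2::xml_text(child), ot = "literal",
             dt = if (is.na(dt)) NA_character_ else dt)
      }
    }
  }
  collector_to_tibble(col)
}

# ---- JSON-LD --------------------------------------------------------------

triples_to_jsonld <- function(tr) {
  subjects <- unique(tr$s)
  rows_by_subject <- split(seq_len(nrow(tr)), factor(tr$s, levels = subjects))
  graph <- lapply(seq_along(subjects), function(si) {
    su <- subjects[si]
    rows <- rows_by_subject[[si]]
    node <- list("@id" = su)
    types <- tr$o[rows][tr$p[rows] == RDF_TYPE & tr$ot[rows] == "iri"]
    if (length(types) > 0) node[["@type"]] <- as.list(compact_iri(types))
    for (k in rows) {
      if (tr$p[k] == RDF_TYPE && tr$ot[k] == "iri") next
      key <- compact_iri(tr$p[k])
      val <- if (tr$ot[k] == "literal") {
        if (is.na(tr$dt[k])) tr$o[k]
        else list("@value" = tr$o[k], "@type" = compact_iri(tr$dt[k]))
      } else {
        list("@id" = tr$o[k])
      }
      node[[key]] <- c(node[[key]] %||% list(), list(val))
    }
    node
  })
  out <- list("@context" = as.list(prefix_map()), "@graph" = graph)
  paste0(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = FALSE, digits = NA), "\n")
}

jsonld_to_triples <- function(text) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e) stop("parse error: malformed JSON-LD: ",
                                         conditionMessage(e), call. = FALSE))
  ctx <- x[["@context"]] %||% list()
  pm <- prefix_map()
  for (k in names(ctx)) if (is.character(ctx[[k]])) pm[k] <- ctx[[k]]
  expand <- function(term) {
    if (grepl("^[A-Za-z][A-Za-z0-9_.-]*:[^/]", term) || grepl("^[A-Za-z][A-Za-z0-9_.-]*:$", term)) {
      pfx <- sub(":.*$", "", term)
      if (pfx %in% names(pm)) return(paste0(pm[[pfx]], sub("^[^:]*:", "", term)))
    }
    term
  }
  graph <- x[["@graph"]] %||% list(x)
  col <- new_collector()
  for (node in graph) {
    su <- node[["@id"]] %||% fresh_blank(col)
    for (ty in node[["@type"]] %||% list()) {
      emit(col, su, RDF_TYPE, expand(ty), ot = "iri")
    }
    for (key in setdiff(names(node), c("@id", "@type"))) {
      p <- expand(key)
      vals <- node[[key]]
      if (!is.list(vals) || !is.null(names(vals))) vals <- list(vals)
      for (v in vals) {
        if (is.character(v) && length(v) == 1) {
          emit(col, su, p, v, ot = "literal")
        } else if (is.list(v) && !is.null(v[["@id"]])) {
          emit(col, su, p, v[["@id"]], ot = "iri")
        } else if (is.list(v) && !is.null(v[["@value"]])) {
          dt <- v[["@type"]]
          emit(col, su, p, as.character(v[["@value"]]), ot = "literal",
               dt = if (is.null(dt)) NA_character_ else expand(dt))
        } else if (is.numeric(v)) {
          emit(col, su, p, fmt_num(v), ot = "literal", dt = x_("double"))
        }
      }
    }
  }
  collector_to_tibble(col)
}

# ---- public surface -------------------------------------------------------

#' Serialize a document to RDF text
#'
#' Refuses documents with ERROR-severity violations. Output is deterministic:
#' serializing the same document twice yields byte-identical text.
#'
#' @param doc A `dnmso_document`.
#' @param dialect `"turtle"` (default), `"rdfxml"` or `"jsonld"`.
#' @return A single string of RDF text in the chosen dialect.
#' @export
serialize_dnmso <- function(doc, dialect = c("turtle", "rdfxml", "jsonld")) {
  dialect <- match.arg(dialect)
  v <- validate_document(doc)
  errs <- v[v$severity == "ERROR", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("refusing to serialize an invalid document:\n",
         paste(sprintf("  [%s] %s", errs$rule, errs$message), collapse = "\n"),
         call. = FALSE)
  }
  tr <- document_to_triples(doc)
  switch(dialect,
         turtle = triples_to_turtle(tr),
         rdfxml = triples_to_rdfxml(tr),
         jsonld = triples_to_jsonld(tr))
}

#' Deserialize a document from RDF text
#'
#' The inverse of [serialize_dnmso()]: `deserialize_dnmso(serialize_dnmso(doc))`
#' is semantically equal to `doc` ([semantic_equal()]). Structurally invalid
#' content (e.g. a prediction without a spectrum link) is loaded and left for
#' [validate_document()] to report; foreign-namespace triples are preserved.
#'
#' @param text RDF text.
#' @param dialect `"turtle"`, `"rdfxml"` or `"jsonld"`.
#' @return A `dnmso_document`.
#' @export
deserialize_dnmso <- function(text, dialect = c("turtle", "rdfxml", "jsonld")) {
  dialect <- match.arg(dialect)
  tr <- switch(dialect,
               turtle = turtle_to_triples(text),
               rdfxml = rdfxml_to_triples(text),
               jsonld = jsonld_to_triples(text))
  triples_to_document(tr)
}

dialect_for_path <- function(path) {
  switch(tolower(tools::file_ext(path)),
         ttl = "turtle", turtle = "turtle",
         rdf = "rdfxml", xml = "rdfxml",
         jsonld = "jsonld", json = "jsonld",
         "turtle")
}

#' Read / write DNMSO files
#'
#' File-level wrappers around [serialize_dnmso()] and [deserialize_dnmso()];
#' the dialect is inferred from the extension (`.ttl`, `.rdf`, `.jsonld`)
#' unless given.
#'
#' @param doc A `dnmso_document`.
#' @param path File path.
#' @param dialect RDF dialect, or `NULL` to infer from the extension.
#' @return `write_dnmso()`: the path, invisibly; `read_dnmso()`: a document.
#' @export
write_dnmso <- function(doc, path, dialect = NULL) {
  dialect <- dialect %||% dialect_for_path(path)
  writeLines(serialize_dnmso(doc, dialect), path, sep = "")
  invisible(path)
}

#' @rdname write_dnmso
#' @export
read_dnmso <- function(path, dialect = NULL) {
  dialect <- dialect %||% dialect_for_path(path)
  deserialize_dnmso(paste(readLines(path, warn = FALSE), collapse = "\n"),
                    dialect)
}

# ---- semantic equality ----------------------------------------------------

num_eq <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (is.na(a) && is.na(b)) return(TRUE)
  if (is.na(a) || is.na(b)) return(FALSE)
  a == b
}

chr_eq <- function(a, b) identical(a %||% NULL, b %||% NULL)

#' Are two documents semantically equal?
#'
#' Canonical deep comparison: same local ids, provenance, spectra (including
#' exact peak values and order), predictions (sequence structure, scores,
#' source references, rank), modifications, software, CV registry and
#' foreign-namespace triples (compared as a set with blank labels
#' normalized). Used as the round-trip oracle.
#'
#' @param a,b `dnmso_document` objects.
#' @return Logical scalar.
#' @export
semantic_equal <- function(a, b) {
  stopifnot(inherits(a, "dnmso_document"), inherits(b, "dnmso_document"))
  if (!chr_eq(a$id, b$id)) return(FALSE)
  if (!chr_eq(a$provenance$creator, b$provenance$creator)) return(FALSE)
  if (!chr_eq(a$provenance$created, b$provenance$created)) return(FALSE)
  if (!identical(names(a$spectra), names(b$spectra))) return(FALSE)
  if (!identical(names(a$predictions), names(b$predictions))) return(FALSE)
  if (!identical(names(a$modifications), names(b$modifications))) return(FALSE)
  if (!identical(names(a$software), names(b$software))) return(FALSE)
  if (!identical(names(a$cv_registry), names(b$cv_registry))) return(FALSE)
  for (id in names(a$spectra)) {
    x <- a$spectra[[id]]; y <- b$spectra[[id]]
    if (!num_eq(x$precursor_mz, y$precursor_mz)) return(FALSE)
    if (!num_eq(x$precursor_charge, y$precursor_charge)) return(FALSE)
    if (nrow(x$peaks) != nrow(y$peaks)) return(FALSE)
    if (nrow(x$peaks) > 0 &&
        (!all(x$peaks$mz == y$peaks$mz) || !all(x$peaks$intensity == y$peaks$intensity))) return(FALSE)
    if (!identical(is.null(x$external_ref), is.null(y$external_ref))) return(FALSE)
    if (!is.null(x$external_ref) &&
        !identical(unclass(x$external_ref), unclass(y$external_ref))) return(FALSE)
    if (!chr_eq(x$native_id, y$native_id)) return(FALSE)
    if (!num_eq(x$retention_time_s, y$retention_time_s)) return(FALSE)
    if (!chr_eq(x$fragmentation, y$fragmentation)) return(FALSE)
  }
  for (id in names(a$predictions)) {
    x <- a$predictions[[id]]; y <- b$predictions[[id]]
    if (!identical(x$source_spectrum_refs, y$source_spectrum_refs)) return(FALSE)
    if (!chr_eq(x$software_ref, y$software_ref)) return(FALSE)
    if (!num_eq(x$rank, y$rank)) return(FALSE)
    if (length(x$scores) != length(y$scores)) return(FALSE)
    for (k in seq_along(x$scores)) {
      if (!chr_eq(x$scores[[k]]$name, y$scores[[k]]$name)) return(FALSE)
      if (!num_eq(x$scores[[k]]$value, y$scores[[k]]$value)) return(FALSE)
      if (!chr_eq(x$scores[[k]]$cv_accession, y$scores[[k]]$cv_accession)) return(FALSE)
    }
    if (!sequences_identical(x$sequence, y$sequence)) return(FALSE)
  }
  for (id in names(a$modifications)) {
    x <- a$modifications[[id]]; y <- b$modifications[[id]]
    if (!chr_eq(x$psimod_accession, y$psimod_accession)) return(FALSE)
    if (!num_eq(x$mono_mass_delta, y$mono_mass_delta)) return(FALSE)
    if (!num_eq(x$avg_mass_delta, y$avg_mass_delta)) return(FALSE)
    if (!chr_eq(paste(x$residue_specificity, collapse = ""),
                paste(y$residue_specificity, collapse = ""))) return(FALSE)
    if (!chr_eq(x$terminus, y$terminus)) return(FALSE)
  }
  for (id in names(a$software)) {
    x <- a$software[[id]]; y <- b$software[[id]]
    if (!chr_eq(x$name, y$name) || !chr_eq(x$version, y$version)) return(FALSE)
    if (length(x$parameters) != length(y$parameters)) return(FALSE)
  }
  identical(canonical_extras(a$extra_triples), canonical_extras(b$extra_triples))
}

canonical_extras <- function(tr) {
  if (nrow(tr) == 0) return(character(0))
  # normalize blank labels by order of first appearance
  labels <- unique(c(tr$s[startsWith(tr$s, "_:")], tr$o[tr$ot == "iri" & startsWith(tr$o, "_:")]))
  remap <- stats::setNames(paste0("_:x", seq_along(labels)), labels)
  s <- ifelse(tr$s %in% names(remap), remap[tr$s], tr$s)
  o <- ifelse(tr$ot == "iri" & tr$o %in% names(remap), remap[tr$o], tr$o)
  sort(paste(s, tr$p, o, tr$ot, ifelse(is.na(tr$dt), "", tr$dt), sep = "\r"))
}
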