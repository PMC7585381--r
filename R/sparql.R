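# A basic-graph-pattern SPARQL SELECT engine over the document's triple
# table: PREFIX declarations, variable/IRI/literal terms, '.'-separated
# triple patterns joined on shared variables, DISTINCT. Enough to express
# the navigation and consensus-style queries the format is meant for.

sparql_tokenize <- function(text) {
  re <- paste0('<[^>]*>',
               '|"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^\\S+)?',
               '|\\?[A-Za-z_][A-Za-z0-9_]*',
               '|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*',
               '|[A-Za-z][A-Za-z0-9_.-]*:',
               '|[+-]?[0-9]+(?:\\.[0-9]+)?',
               '|[A-Za-z]+|[{}.*]')
  m <- gregexpr(re, text, perl = TRUE)[[1]]
  list(tokens = regmatches(text, list(m))[[1]], positions = as.integer(m))
}

#' Run a SPARQL SELECT query over a document
#'
#' Serializes the document to its RDF graph and evaluates the query with
#' standard SELECT semantics over basic graph patterns (`PREFIX`
#' declarations, `DISTINCT`, `*` projection). Patterns over namespaces the
#' graph does not use simply yield an empty result.
#'
#' @param doc A `dnmso_document`.
#' @param query SPARQL SELECT text.
#' @return A tibble of bindings, one column per projected variable.
#' @examples
#' doc <- dnmso_document("ex") |>
#'   add_spectrum(spectrum(500, 2, peaks = data.frame(mz = 1, intensity = 1))) |>
#'   add_prediction(prediction(pep_sequence("PEP"), score("s", 1), "SPEC_1"))
#' run_query(doc, "SELECT ?p WHERE { ?p a dnmso:Prediction }")
#' @export
run_query <- function(doc, query) {
  stopifnot(inherits(doc, "dnmso_document"))
  tr <- document_to_triples(doc)
  tk <- sparql_tokenize(query)
  toks <- tk$tokens
  pos <- tk$positions
  i <- 1L
  fail <- function(msg, at = i) {
    p <- if (at <= length(pos)) pos[at] else nchar(query)
    stop("query error at position ", p, ": ", msg, call. = FALSE)
  }
  peek <- function() if (i <= length(toks)) toks[i] else ""
  nxt <- function() {
    if (i > length(toks)) fail("unexpected end of query")
    t <- toks[i]; i <<- i + 1L; t
  }
  pm <- prefix_map()
  while (toupper(peek()) == "PREFIX") {
    nxt()
    pdecl <- nxt()
    iri <- nxt()
    if (!grepl(":$", pdecl) || !grepl("^<.*>$", iri)) fail("malformed PREFIX")
    pm[sub(":$", "", pdecl)] <- substr(iri, 2, nchar(iri) - 1L)
  }
  if (toupper(nxt()) != "SELECT") fail("expected SELECT", i - 1L)
  distinct <- FALSE
  if (toupper(peek()) == "DISTINCT") { distinct <- TRUE; nxt() }
  proj <- character(0)
  star <- FALSE
  while (startsWith(peek(), "?") || peek() == "*") {
    t <- nxt()
    if (t == "*") star <- TRUE else proj <- c(proj, substring(t, 2))
  }
  if (!star && length(proj) == 0) fail("no projection variables")
  if (toupper(nxt()) != "WHERE") fail("expected WHERE", i - 1L)
  if (nxt() != "{") fail("expected '{'", i - 1L)
  patterns <- list()
  term <- function() {
    t <- nxt()
    if (startsWith(t, "?")) return(list(var = substring(t, 2)))
    if (t == "a") return(list(value = RDF_TYPE, literal = FALSE))
    if (grepl("^<.*>$", t)) return(list(value = substr(t, 2, nchar(t) - 1L), literal = FALSE))
    if (startsWith(t, '"')) {
      body <- sub('\\^\\^\\S+$', "", t)
      return(list(value = unescape_ttl(substr(body, 2, nchar(body) - 1L)), literal = TRUE))
    }
    if (grepl("^[+-]?[0-9]", t)) return(list(value = t, literal = TRUE))
    if (grepl(":", t, fixed = TRUE)) {
      ex <- expand_prefixed(t, pm)
      if (identical(ex, t)) fail(paste0("undefined prefix in '", t, "'"), i - 1L)
      return(list(value = ex, literal = FALSE))
    }
    fail(paste0("unexpected token '", t, "'"), i - 1L)
  }
  while (peek() != "}") {
    if (peek() == "") fail("unterminated group pattern")
    s <- term(); p <- term(); o <- term()
    patterns[[length(patterns) + 1L]] <- list(s = s, p = p, o = o)
    if (peek() == ".") nxt()
  }
  nxt() # }
  if (length(patterns) == 0) fail("empty group pattern")

  bindings <- match_bgp(tr, patterns)
  vars <- if (star) names(bindings) else proj
  missing <- setdiff(vars, names(bindings))
  for (v in missing) bindings[[v]] <- character(0)
  out <- bindings[, vars, drop = FALSE]
  if (distinct) out <- dplyr::distinct(out)
  tibble::as_tibble(out)
}

match_bgp <- function(tr, patterns) {
  solutions <- NULL # data frame of variable bindings
  for (pat in patterns) {
    keep <- rep(TRUE, nrow(tr))
    for (slot in c("s", "p", "o")) {
      t <- pat[[slot]]
      if (!is.null(t$value)) {
        col <- tr[[slot]]
        if (slot == "o") {
          want_lit <- isTRUE(t$literal)
          keep <- keep & (tr$ot == if (want_lit) "literal" else "iri") & col == t$value
        } else {
          keep <- keep & col == t$value
        }
      }
    }
    rows <- tr[keep, , drop = FALSE]
    part <- list()
    for (slot in c("s", "p", "o")) {
      t <- pat[[slot]]
      if (!is.null(t$var)) part[[t$var]] <- rows[[slot]]
    }
    part <- tibble::as_tibble(part[!duplicated(names(part))])
    if (ncol(part) == 0) {
      if (nrow(rows) == 0) return(tibble::tibble()[0, ])
      next
    }
    solutions <- if (is.null(solutions)) part
                 else if (length(intersect(names(solutions), names(part))) > 0) {
                   dplyr::inner_join(solutions, part,
                                     by = intersect(names(solutions), names(part)))
                 } else {
                   dplyr::cross_join(solutions, part)
                 }
    if (nrow(solutions) == 0) break
  }
  solutions %||% tibble::tibble()
}
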