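# Score-threshold filtering: named scores with greater / lesser / equal
# (and the non-strict variants) constraints, combinable with all/any.
# Filtering keeps every spectrum — spectra may be orphaned, predictions may
# not — so the result is always a valid document.

COMPARATORS <- c("greater", "lesser", "equal", "greater_or_equal", "lesser_or_equal")

#' Score constraint
#'
#' @param score_name Non-empty name of the score to test.
#' @param comparator One of `"greater"`, `"lesser"`, `"equal"`,
#'   `"greater_or_equal"`, `"lesser_or_equal"`.
#' @param threshold Finite threshold value.
#' @return A `dnmso_score_constraint`.
#' @examples
#' score_constraint("RnkScr", "greater_or_equal", 0.5)
#' parse_constraint("RnkScr>=0.5")
#' @export
score_constraint <- function(score_name, comparator = COMPARATORS, threshold) {
  comparator <- match.arg(comparator)
  if (!is.character(score_name) || length(score_name) != 1 || !nzchar(score_name)) {
    stop("score_name must be non-empty", call. = FALSE)
  }
  if (!is.numeric(threshold) || !is.finite(threshold)) {
    stop("threshold must be finite", call. = FALSE)
  }
  structure(list(score_name = score_name, comparator = comparator,
                 threshold = as.numeric(threshold)),
            class = "dnmso_score_constraint")
}

#' @rdname score_constraint
#' @param expr Constraint expression `<name><op><number>` with op one of
#'   `>`, `<`, `=`, `>=`, `<=` (e.g. `"RnkScr>=0.5"`).
#' @export
parse_constraint <- function(expr) {
  m <- regmatches(expr, regexec("^\\s*([^<>=]+?)\\s*(>=|<=|>|<|=)\\s*([-+0-9.eE]+)\\s*$", expr))[[1]]
  if (length(m) == 0) {
    stop("usage error: cannot parse constraint '", expr,
         "' (expected <name><op><number>)", call. = FALSE)
  }
  cmp <- switch(m[3], ">" = "greater", "<" = "lesser", "=" = "equal",
                ">=" = "greater_or_equal", "<=" = "lesser_or_equal")
  value <- suppressWarnings(as.numeric(m[4]))
  if (is.na(value)) stop("usage error: bad threshold in '", expr, "'", call. = FALSE)
  score_constraint(m[2], cmp, value)
}

constraint_holds <- function(p, ct) {
  vals <- vapply(p$scores, function(s) if (identical(s$name, ct$score_name)) s$value else NA_real_,
                 numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(FALSE) # missing score fails the constraint
  v <- vals[1]
  switch(ct$comparator,
         greater = v > ct$threshold,
         lesser = v < ct$threshold,
         equal = v == ct$threshold,
         greater_or_equal = v >= ct$threshold,
         lesser_or_equal = v <= ct$threshold)
}

#' Filter predictions by score constraints
#'
#' Returns a new document containing exactly the predictions that satisfy
#' the combined constraints, and *all* spectra (orphan spectra are legal;
#' orphan predictions are not, so predictions are never left dangling). A
#' prediction lacking the named score fails that constraint. Idempotent:
#' filtering twice with the same constraints changes nothing.
#'
#' @param doc A `dnmso_document`.
#' @param constraints A [score_constraint()], a list of them, or character
#'   expressions for [parse_constraint()]. Must be non-empty.
#' @param combine `"all"` (conjunction, default) or `"any"` (disjunction).
#' @return A new `dnmso_document` (an empty prediction set is valid).
#' @export
filter_predictions <- function(doc, constraints, combine = c("all", "any")) {
  combine <- match.arg(combine)
  stopifnot(inherits(doc, "dnmso_document"))
  if (inherits(constraints, "dnmso_score_constraint")) constraints <- list(constraints)
  if (is.character(constraints)) constraints <- lapply(constraints, parse_constraint)
  if (length(constraints) == 0) stop("constraints must be non-empty", call. = FALSE)
  ok <- vapply(doc$predictions, function(p) {
    hits <- vapply(constraints, function(ct) constraint_holds(p, ct), logical(1))
    if (combine == "all") all(hits) else any(hits)
  }, logical(1))
  out <- doc
  out$predictions <- doc$predictions[ok]
  attr(out, "last_id") <- NULL
  out
}
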