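# Spectra: one MS/MS scan each, represented either by an inline peak list
# (the CSV self-containment mechanism) or by a reference into an external
# peak-list file. Both may be present; at least one must be.

#' Reference to a spectrum stored in an external file
#'
#' @param file_path_or_uri Path or URI of the peak-list file.
#' @param format_hint One of `"mzML"`, `"mzXML"`, `"MGF"`, `"other"`.
#' @param native_id Non-empty scan identifier within that file.
#' @return A `dnmso_external_ref`.
#' @export
external_ref <- function(file_path_or_uri,
                         format_hint = c("mzML", "mzXML", "MGF", "other"),
                         native_id) {
  format_hint <- match.arg(format_hint)
  if (!is.character(native_id) || length(native_id) != 1 || !nzchar(native_id)) {
    stop("external reference requires a non-empty native_id", call. = FALSE)
  }
  structure(list(file_path_or_uri = file_path_or_uri,
                 format_hint = format_hint, native_id = native_id),
            class = "dnmso_external_ref")
}

empty_peaks <- function() {
  tibble::tibble(mz = numeric(0), intensity = numeric(0))
}

as_peaks <- function(peaks) {
  if (is.null(peaks)) return(empty_peaks())
  peaks <- tibble::as_tibble(as.data.frame(peaks))
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    stop("structural error: peaks need columns mz and intensity", call. = FALSE)
  }
  peaks <- peaks[, c("mz", "intensity")]
  peaks$mz <- as.numeric(peaks$mz)
  peaks$intensity <- as.numeric(peaks$intensity)
  peaks
}

check_peaks <- function(peaks, normalize = FALSE) {
  if (nrow(peaks) == 0) return(peaks)
  if (any(!is.finite(peaks$mz)) || any(!is.finite(peaks$intensity))) {
    stop("structural error: peaks must have finite values", call. = FALSE)
  }
  if (any(peaks$mz <= 0)) {
    stop("structural error: all peak m/z must be > 0", call. = FALSE)
  }
  if (any(peaks$intensity < 0)) {
    stop("structural error: peak intensities must be >= 0", call. = FALSE)
  }
  if (is.unsorted(peaks$mz)) {
    if (!normalize) {
      stop("structural error: peaks must be sorted by ascending m/z", call. = FALSE)
    }
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
  }
  peaks
}

#' Create a spectrum
#'
#' @param precursor_mz Precursor mass-to-charge in Thomson, `> 0` (or `NA`
#'   when unknown).
#' @param precursor_charge Positive integer charge, or `NA` for unknown.
#'   Tools that omit the charge yield `NA`; it is never guessed.
#' @param peaks Data frame with columns `mz`, `intensity`; must be sorted by
#'   ascending m/z unless `normalize = TRUE`. May be empty only when
#'   `external_ref` is given.
#' @param external_ref Optional [external_ref()].
#' @param id Local id (auto-assigned by [add_spectrum()] when `NULL`).
#' @param native_id Optional scan identifier from the source file.
#' @param retention_time_s Optional retention time in seconds.
#' @param fragmentation Optional tag: `"CID"`, `"ETD"`, `"HCD"` or `"other"`.
#' @param normalize Sort unsorted peak lists instead of rejecting them (used
#'   by file readers; the construction API itself enforces sortedness).
#' @return A `dnmso_spectrum`.
#' @examples
#' spectrum(500.25, 2, peaks = data.frame(mz = c(100, 200), intensity = c(1, 2)))
#' @export
spectrum <- function(precursor_mz = NA_real_, precursor_charge = NA_integer_,
                     peaks = NULL, external_ref = NULL, id = NULL,
                     native_id = NULL, retention_time_s = NULL,
                     fragmentation = NULL, normalize = FALSE) {
  peaks <- check_peaks(as_peaks(peaks), normalize = normalize)
  if (nrow(peaks) == 0 && is.null(external_ref)) {
    stop("structural error: a spectrum needs inline peaks or an external reference",
         call. = FALSE)
  }
  if (!is.null(external_ref) && !inherits(external_ref, "dnmso_external_ref")) {
    stop("external_ref must be built with external_ref()", call. = FALSE)
  }
  if (!is.na(precursor_mz) && (!is.finite(precursor_mz) || precursor_mz <= 0)) {
    stop("structural error: precursor_mz must be > 0", call. = FALSE)
  }
  if (!is.na(precursor_charge)) {
    precursor_charge <- as.integer(precursor_charge)
    if (is.na(precursor_charge) || precursor_charge < 1) {
      stop("structural error: precursor_charge must be a positive integer or NA",
           call. = FALSE)
    }
  }
  if (!is.null(fragmentation) &&
      !fragmentation %in% c("CID", "ETD", "HCD", "other")) {
    stop("fragmentation must be one of CID, ETD, HCD, other", call. = FALSE)
  }
  structure(
    list(id = id, precursor_mz = as.numeric(precursor_mz),
         precursor_charge = precursor_charge, peaks = peaks,
         external_ref = external_ref, native_id = native_id,
         retention_time_s = retention_time_s, fragmentation = fragmentation),
    class = "dnmso_spectrum"
  )
}

has_inline_peaks <- function(s) nrow(s$peaks) > 0

#' @export
print.dnmso_spectrum <- function(x, ...) {
  src <- if (has_inline_peaks(x)) sprintf("%d inline peaks", nrow(x$peaks))
         else sprintf("external %s '%s'", x$external_ref$format_hint,
                      x$external_ref$native_id)
  cat(sprintf("<spectrum %s> precursor %.4f Th, charge %s, %s\n",
              x$id %||% "?", x$precursor_mz,
              ifelse(is.na(x$precursor_charge), "unknown", x$precursor_charge),
              src))
  invisible(x)
}

#' Score attached to a prediction
#'
#' @param name Non-empty score label (tool specific, e.g. `"RnkScr"`).
#' @param value Real-valued score.
#' @param cv_accession Optional controlled-vocabulary accession for the score
#'   term (pattern `PREFIX:digits`).
#' @return A `dnmso_score`.
#' @export
score <- function(name, value, cv_accession = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("missing-score error: score name must be non-empty", call. = FALSE)
  }
  if (!is.numeric(value) || length(value) != 1 || is.na(value)) {
    stop("score value must be a number", call. = FALSE)
  }
  structure(list(name = name, value = as.numeric(value),
                 cv_accession = cv_accession),
            class = "dnmso_score")
}

#' A peptide-spectrum-match prediction
#'
#' A prediction pairs one candidate [pep_sequence()] with at least one score
#' and at least one source spectrum. The spectrum link is many-to-many: a
#' prediction may be sourced from several spectra (e.g. CID and ETD scans of
#' the same precursor), and a spectrum may back many predictions.
#'
#' @param sequence A [pep_sequence()].
#' @param scores A [score()] or list of scores; at least one.
#' @param source_spectrum_refs Character vector of spectrum ids; at least one.
#' @param software_ref Optional local id of the producing [software()].
#' @param rank Optional positive integer; 1 = best candidate for its source
#'   spectrum set.
#' @param id Local id (auto-assigned by [add_prediction()] when `NULL`).
#' @return A `dnmso_prediction`.
#' @export
prediction <- function(sequence, scores, source_spectrum_refs,
                       software_ref = NULL, rank = NULL, id = NULL) {
  stopifnot(inherits(sequence, "dnmso_sequence"))
  if (inherits(scores, "dnmso_score")) scores <- list(scores)
  if (length(scores) == 0 ||
      !all(vapply(scores, inherits, logical(1), "dnmso_score"))) {
    stop("missing-score error: a prediction needs at least one score",
         call. = FALSE)
  }
  refs <- as.character(source_spectrum_refs)
  if (length(refs) == 0 || any(!nzchar(refs))) {
    stop("orphan-prediction error: a prediction needs at least one source spectrum",
         call. = FALSE)
  }
  if (!is.null(rank)) {
    rank <- as.integer(rank)
    if (is.na(rank) || rank < 1) stop("rank must be a positive integer", call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, scores = scores,
         source_spectrum_refs = refs, software_ref = software_ref, rank = rank),
    class = "dnmso_prediction"
  )
}

#' @export
print.dnmso_prediction <- function(x, ...) {
  cat(sprintf("<prediction %s> %s  [%s]  <- %s\n", x$id %||% "?",
              render_sequence(x$sequence),
              paste(vapply(x$scores, function(s) sprintf("%s=%g", s$name, s$value),
                           character(1)), collapse = ", "),
              paste(x$source_spectrum_refs, collapse = ",")))
  invisible(x)
}

#' Software entry
#'
#' @param name Non-empty tool name.
#' @param version Version text.
#' @param parameters Optional list of [cv_param()] or plain `key = value`
#'   pairs.
#' @param id Local id; defaults to the name.
#' @return A `dnmso_software`.
#' @export
software <- function(name, version = "", parameters = list(), id = name) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("software name must be non-empty", call. = FALSE)
  }
  structure(list(id = id, name = name, version = version,
                 parameters = parameters),
            class = "dnmso_software")
}

#' Controlled-vocabulary parameter
#'
#' @param cv_ref Id of a [cv_source()] in the document registry.
#' @param accession Term accession, pattern `PREFIX:digits`.
#' @param name Term name.
#' @param value Optional value text.
#' @return A `dnmso_cv_param`.
#' @export
cv_param <- function(cv_ref, accession, name, value = NULL) {
  if (!grepl("^[A-Za-z][A-Za-z0-9-]*:[0-9]+$", accession)) {
    stop("cv accession must match PREFIX:digits", call. = FALSE)
  }
  structure(list(cv_ref = cv_ref, accession = accession, name = name,
                 value = value),
            class = "dnmso_cv_param")
}

#' Controlled-vocabulary source
#'
#' @param id Registry id, e.g. `"PSI-MS"`, `"PSI-MOD"`.
#' @param full_name Full vocabulary name.
#' @param version Version text.
#' @param uri Vocabulary URI.
#' @return A `dnmso_cv_source`.
#' @export
cv_source <- function(id, full_name = id, version = "", uri = "") {
  structure(list(id = id, full_name = full_name, version = version, uri = uri),
            class = "dnmso_cv_source")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
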