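# Spectra ingestion. MGF, mzML 1.1 and mzXML 3.x are read into spectrum
# objects; matching minimal writers exist so the synthetic-data generator can
# produce the same scan in every format. Readers normalize peak order and
# yield only MS-level-2 scans from the XML formats.

fmt_num <- function(x) {
  # shortest representation that round-trips IEEE doubles exactly
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

# ---- MGF ------------------------------------------------------------------

parse_mgf_charge <- function(txt) {
  txt <- trimws(txt)
  if (grepl("^[0-9]+\\+?$", txt)) {
    return(as.integer(sub("\\+", "", txt)))
  }
  warning("ambiguous or non-positive MGF CHARGE '", txt,
          "'; precursor charge set to unknown", call. = FALSE)
  NA_integer_
}

#' Read spectra from a Mascot Generic Format file
#'
#' One spectrum per `BEGIN IONS`/`END IONS` block. `TITLE` becomes the
#' spectrum's `native_id` (and local id), the first `PEPMASS` token the
#' precursor m/z, `CHARGE "2+"` charge 2; a charge list ("2+ and 3+") or
#' absent charge yields unknown. Peaks are sorted by m/z.
#'
#' @param path Path to an MGF file.
#' @return List of [spectrum()] objects (empty for an empty file).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  in_block <- FALSE
  block_index <- 0L
  hdr <- list()
  mz <- numeric(0); int <- numeric(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stop("truncation error: block ", block_index,
                         " missing END IONS", call. = FALSE)
      in_block <- TRUE
      block_index <- block_index + 1L
      hdr <- list(); mz <- numeric(0); int <- numeric(0)
    } else if (line == "END IONS") {
      if (!in_block) stop("parse error at line ", ln, ": END IONS without BEGIN IONS",
                          call. = FALSE)
      in_block <- FALSE
      charge <- if (!is.null(hdr$CHARGE)) parse_mgf_charge(hdr$CHARGE) else NA_integer_
      pep <- if (!is.null(hdr$PEPMASS)) {
        as.numeric(strsplit(trimws(hdr$PEPMASS), "[ \t]+")[[1]][1])
      } else NA_real_
      title <- hdr$TITLE %||% paste0("index=", block_index - 1L)
      rt <- if (!is.null(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS) else NULL
      out[[length(out) + 1L]] <- spectrum(
        precursor_mz = pep, precursor_charge = charge,
        peaks = tibble::tibble(mz = mz, intensity = int),
        id = title, native_id = title, retention_time_s = rt,
        normalize = TRUE
      )
    } else if (in_block && grepl("=", line, fixed = TRUE)) {
      kv <- regmatches(line, regexpr("=", line, fixed = TRUE), invert = TRUE)[[1]]
      hdr[[kv[1]]] <- kv[2]
    } else if (in_block) {
      tok <- strsplit(line, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(tok[1:2]))
      if (length(tok) < 2 || any(is.na(vals))) {
        stop("parse error at line ", ln, ": non-numeric peak line '", line, "'",
             call. = FALSE)
      }
      mz <- c(mz, vals[1]); int <- c(int, vals[2])
    }
    # content outside blocks is ignored (MGF permits global headers)
  }
  if (in_block) stop("truncation error: block ", block_index,
                     " missing END IONS", call. = FALSE)
  out
}

#' Write spectra to MGF
#'
#' @param spectra List of [spectrum()] objects with inline peaks.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$native_id %||% s$id %||% ""), con)
    if (!is.na(s$precursor_mz)) writeLines(paste0("PEPMASS=", fmt_num(s$precursor_mz)), con)
    if (!is.na(s$precursor_charge)) writeLines(paste0("CHARGE=", s$precursor_charge, "+"), con)
    if (!is.null(s$retention_time_s)) writeLines(paste0("RTINSECONDS=", fmt_num(s$retention_time_s)), con)
    if (nrow(s$peaks) > 0) {
      writeLines(paste(fmt_num(s$peaks$mz), fmt_num(s$peaks$intensity)), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

# ---- binary peak arrays ---------------------------------------------------

encode_doubles_b64 <- function(x, size = 8, endian = "little") {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = size, endian = endian))
}

decode_doubles_b64 <- function(txt, n, size = 8, endian = "little",
                               compressed = FALSE) {
  b <- jsonlite::base64_dec(gsub("[\r\n ]", "", txt))
  if (compressed) b <- memDecompress(b, type = "gzip")
  readBin(b, "double", n = n, size = size, endian = endian)
}

# ---- mzML -----------------------------------------------------------------

MZML_NS <- "http://psi.hupo.org/ms/mzml"

#' Read MS2 spectra from an mzML file
#'
#' Yields only MS-level-2 scans. The scan's `id` attribute is preserved as
#' `native_id`; precursor m/z (MS:1000744) and charge state (MS:1000041) are
#' extracted when present — an MS2 scan without precursor information is
#' yielded with unknown precursor and a warning. 64- and 32-bit float peak
#' arrays are supported, with optional zlib compression.
#'
#' @param path Path to an mzML file.
#' @return List of [spectrum()] objects.
#' @export
read_mzml <- function(path) {
  xml <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error: malformed XML: ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(xml)
  out <- list()
  for (sp in xml2::xml_find_all(xml, ".//spectrumList/spectrum")) {
    lvl <- cv_value(sp, "MS:1000511", children_only = TRUE)
    if (is.na(lvl) || as.integer(lvl) != 2L) next
    native_id <- xml2::xml_attr(sp, "id")
    ion <- xml2::xml_find_first(sp, ".//selectedIon")
    if (inherits(ion, "xml_missing")) {
      warning("MS2 scan '", native_id, "' lacks precursor information",
              call. = FALSE)
      pmz <- NA_real_; charge <- NA_integer_
    } else {
      pmz <- as.numeric(cv_value(ion, "MS:1000744"))
      ch <- cv_value(ion, "MS:1000041")
      charge <- if (is.na(ch)) NA_integer_ else as.integer(ch)
    }
    rt <- NULL
    rt_node <- xml2::xml_find_first(sp, ".//scan/cvParam[@accession='MS:1000016']")
    if (!inherits(rt_node, "xml_missing")) {
      rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
      if (identical(xml2::xml_attr(rt_node, "unitName"), "minute")) rt <- rt * 60
    }
    n <- as.integer(xml2::xml_attr(sp, "defaultArrayLength"))
    arrays <- list()
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      size <- if (cv_has(bda, "MS:1000521")) 4 else 8
      compressed <- cv_has(bda, "MS:1000574")
      kind <- if (cv_has(bda, "MS:1000514")) "mz"
              else if (cv_has(bda, "MS:1000515")) "intensity"
              else next
      b64 <- xml2::xml_text(xml2::xml_find_first(bda, "./binary"))
      arrays[[kind]] <- decode_doubles_b64(b64, n = n, size = size,
                                           compressed = compressed)
    }
    pk <- tibble::tibble(mz = arrays$mz %||% numeric(0),
                         intensity = arrays$intensity %||% numeric(0))
    if (nrow(pk) == 0) {
      warning("MS2 scan '", native_id, "' has zero peaks", call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- spectrum(
      precursor_mz = pmz, precursor_charge = charge, peaks = pk,
      id = native_id, native_id = native_id, retention_time_s = rt,
      normalize = TRUE)
  }
  out
}

cv_has <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession)), "xml_missing")
}

cv_value <- function(node, accession, children_only = FALSE) {
  xp <- if (children_only) sprintf("./cvParam[@accession='%s']", accession)
        else sprintf(".//cvParam[@accession='%s']", accession)
  n <- xml2::xml_find_first(node, xp)
  if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
}

#' Write spectra to a minimal mzML 1.1 instance
#'
#' @inheritParams write_mgf
#' @param ms1_stub Also emit a synthetic MS1 survey scan before the MS2 scans
#'   (exercises the reader's MS-level filter).
#' @export
write_mzml <- function(spectra, path, ms1_stub = FALSE) {
  scans <- character(0)
  idx <- 0L
  cvp <- function(acc, name, value = NULL) {
    sprintf('<cvParam cvRef="MS" accession="%s" name="%s"%s/>', acc, name,
            if (is.null(value)) "" else sprintf(' value="%s"', value))
  }
  if (ms1_stub) {
    scans <- c(scans, sprintf(
      '<spectrum index="%d" id="scan=0" defaultArrayLength="1">%s<binaryDataArrayList count="2"><binaryDataArray encodedLength="0">%s%s%s<binary>%s</binary></binaryDataArray><binaryDataArray encodedLength="0">%s%s%s<binary>%s</binary></binaryDataArray></binaryDataArrayList></spectrum>',
      idx, cvp("MS:1000511", "ms level", "1"),
      cvp("MS:1000523", "64-bit float"), cvp("MS:1000576", "no compression"),
      cvp("MS:1000514", "m/z array"), encode_doubles_b64(400),
      cvp("MS:1000523", "64-bit float"), cvp("MS:1000576", "no compression"),
      cvp("MS:1000515", "intensity array"), encode_doubles_b64(1)))
    idx <- idx + 1L
  }
  for (s in spectra) {
    nid <- s$native_id %||% s$id %||% sprintf("scan=%d", idx + 1L)
    prec <- if (!is.na(s$precursor_mz)) sprintf(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>%s%s</selectedIon></selectedIonList></precursor></precursorList>',
      cvp("MS:1000744", "selected ion m/z", fmt_num(s$precursor_mz)),
      if (!is.na(s$precursor_charge)) cvp("MS:1000041", "charge state", s$precursor_charge) else ""
    ) else ""
    rt <- if (!is.null(s$retention_time_s)) sprintf(
      '<scanList count="1"><scan>%s</scan></scanList>',
      cvp("MS:1000016", "scan start time", fmt_num(s$retention_time_s))) else ""
    scans <- c(scans, sprintf(
      '<spectrum index="%d" id="%s" defaultArrayLength="%d">%s%s%s<binaryDataArrayList count="2"><binaryDataArray>%s%s%s<binary>%s</binary></binaryDataArray><binaryDataArray>%s%s%s<binary>%s</binary></binaryDataArray></binaryDataArrayList></spectrum>',
      idx, nid, nrow(s$peaks), cvp("MS:1000511", "ms level", "2"), rt, prec,
      cvp("MS:1000523", "64-bit float"), cvp("MS:1000576", "no compression"),
      cvp("MS:1000514", "m/z array"), encode_doubles_b64(s$peaks$mz),
      cvp("MS:1000523", "64-bit float"), cvp("MS:1000576", "no compression"),
      cvp("MS:1000515", "intensity array"), encode_doubles_b64(s$peaks$intensity)))
    idx <- idx + 1L
  }
  doc <- sprintf(
    '<?xml version="1.0" encoding="utf-8"?>\n<mzML xmlns="%s" version="1.1.0"><run id="run1"><spectrumList count="%d">%s</spectrumList></run></mzML>\n',
    MZML_NS, idx, paste(scans, collapse = ""))
  writeLines(doc, path, sep = "")
  invisible(path)
}

# ---- mzXML ----------------------------------------------------------------

#' Read MS2 spectra from an mzXML file
#'
#' Only `msLevel="2"` scans are yielded; the `num` attribute becomes
#' `native_id` (`scan=<num>`), precursor m/z and charge come from the
#' `precursorMz` element. Peak arrays are network-byte-order (big-endian)
#' interleaved m/z–intensity pairs at 32- or 64-bit precision.
#'
#' @param path Path to an mzXML file.
#' @return List of [spectrum()] objects.
#' @export
read_mzxml <- function(path) {
  xml <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error: malformed XML: ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(xml)
  out <- list()
  for (scan in xml2::xml_find_all(xml, ".//scan")) {
    if (!identical(xml2::xml_attr(scan, "msLevel"), "2")) next
    num <- xml2::xml_attr(scan, "num")
    native_id <- paste0("scan=", num)
    prec_node <- xml2::xml_find_first(scan, "./precursorMz")
    if (inherits(prec_node, "xml_missing")) {
      warning("MS2 scan ", num, " lacks precursorMz", call. = FALSE)
      pmz <- NA_real_; charge <- NA_integer_
    } else {
      pmz <- as.numeric(xml2::xml_text(prec_node))
      ch <- xml2::xml_attr(prec_node, "precursorCharge")
      charge <- if (is.na(ch)) NA_integer_ else as.integer(ch)
    }
    peaks_node <- xml2::xml_find_first(scan, "./peaks")
    precision <- xml2::xml_attr(peaks_node, "precision")
    size <- if (identical(precision, "32")) 4 else 8
    endian <- if (identical(xml2::xml_attr(peaks_node, "byteOrder"), "little")) "little" else "big"
    n_peaks <- as.integer(xml2::xml_attr(scan, "peaksCount"))
    vals <- decode_doubles_b64(xml2::xml_text(peaks_node), n = 2L * n_peaks,
                               size = size, endian = endian)
    pk <- tibble::tibble(mz = vals[c(TRUE, FALSE)], intensity = vals[c(FALSE, TRUE)])
    rt_txt <- xml2::xml_attr(scan, "retentionTime")
    rt <- if (!is.na(rt_txt)) as.numeric(sub("^PT([0-9.]+)S$", "\\1", rt_txt)) else NULL
    out[[length(out) + 1L]] <- spectrum(
      precursor_mz = pmz, precursor_charge = charge, peaks = pk,
      id = native_id, native_id = native_id, retention_time_s = rt,
      normalize = TRUE)
  }
  out
}

#' Write spectra to a minimal mzXML 3.x instance
#'
#' @inheritParams write_mgf
#' @export
write_mzxml <- function(spectra, path) {
  scans <- character(0)
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    vals <- as.vector(rbind(s$peaks$mz, s$peaks$intensity))
    prec <- if (!is.na(s$precursor_mz)) sprintf(
      '<precursorMz%s>%s</precursorMz>',
      if (!is.na(s$precursor_charge)) sprintf(' precursorCharge="%d"', s$precursor_charge) else "",
      fmt_num(s$precursor_mz)) else ""
    rt <- if (!is.null(s$retention_time_s))
      sprintf(' retentionTime="PT%sS"', fmt_num(s$retention_time_s)) else ""
    scans <- c(scans, sprintf(
      '<scan num="%d" msLevel="2" peaksCount="%d"%s>%s<peaks precision="64" byteOrder="network" contentType="m/z-int">%s</peaks></scan>',
      k, nrow(s$peaks), rt, prec, encode_doubles_b64(vals, endian = "big")))
  }
  doc <- sprintf(
    '<?xml version="1.0" encoding="utf-8"?>\n<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2"><msRun scanCount="%d">%s</msRun></mzXML>\n',
    length(spectra), paste(scans, collapse = ""))
  writeLines(doc, path, sep = "")
  invisible(path)
}

# ---- inline CSV representation -------------------------------------------

peaks_to_csv_body <- function(peaks) {
  if (nrow(peaks) == 0) return("")
  paste(paste(fmt_num(peaks$mz), fmt_num(peaks$intensity), sep = ","),
        collapse = "\n")
}

csv_body_to_peaks <- function(body) {
  if (!nzchar(body)) return(empty_peaks())
  rows <- strsplit(body, "\n", fixed = TRUE)[[1]]
  rows <- rows[nzchar(trimws(rows))]
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop("parse error: ragged CSV row ", bad[1], call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  if (any(is.na(m))) {
    stop("parse error: non-numeric CSV row ",
         which(is.na(m[, 1]) | is.na(m[, 2]))[1], call. = FALSE)
  }
  if (any(m[, 2] < 0)) {
    stop("parse error: negative intensity in CSV row ", which(m[, 2] < 0)[1],
         call. = FALSE)
  }
  tibble::tibble(mz = m[, 1], intensity = m[, 2])
}

#' Spectrum–CSV conversion
#'
#' The inline CSV dialect that makes documents self-contained: `#key=value`
#' header comment lines carrying id, precursor m/z and charge, then one
#' `mz,intensity` line per peak at full precision (bit-exact round-trip).
#' Comma separator, `.` decimal point, LF line endings.
#'
#' @param s A [spectrum()] with inline peaks.
#' @param text CSV text as produced by `spectrum_to_csv()`.
#' @return `spectrum_to_csv()`: a single string; `csv_to_spectrum()`: a
#'   [spectrum()] (unsorted rows are sorted on ingestion).
#' @export
spectrum_to_csv <- function(s) {
  stopifnot(inherits(s, "dnmso_spectrum"))
  if (!has_inline_peaks(s)) {
    stop("structural error: spectrum has no inline peaks", call. = FALSE)
  }
  hdr <- c(paste0("#id=", s$id %||% ""),
           paste0("#precursor_mz=", if (is.na(s$precursor_mz)) "" else fmt_num(s$precursor_mz)),
           paste0("#charge=", if (is.na(s$precursor_charge)) "" else s$precursor_charge))
  if (!is.null(s$native_id)) hdr <- c(hdr, paste0("#native_id=", s$native_id))
  if (!is.null(s$retention_time_s)) hdr <- c(hdr, paste0("#retention_time_s=", fmt_num(s$retention_time_s)))
  if (!is.null(s$fragmentation)) hdr <- c(hdr, paste0("#fragmentation=", s$fragmentation))
  paste0(paste(hdr, collapse = "\n"), "\n", peaks_to_csv_body(s$peaks), "\n")
}

#' @rdname spectrum_to_csv
#' @export
csv_to_spectrum <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  hdr_lines <- grep("^#", lines, value = TRUE)
  body <- paste(lines[!grepl("^#", lines)], collapse = "\n")
  hdr <- list()
  for (h in hdr_lines) {
    kv <- regmatches(h, regexpr("=", h, fixed = TRUE), invert = TRUE)[[1]]
    hdr[[sub("^#", "", kv[1])]] <- kv[2]
  }
  peaks <- csv_body_to_peaks(body)
  spectrum(
    precursor_mz = if (nzchar(hdr$precursor_mz %||% "")) as.numeric(hdr$precursor_mz) else NA_real_,
    precursor_charge = if (nzchar(hdr$charge %||% "")) as.integer(hdr$charge) else NA_integer_,
    peaks = peaks,
    id = if (nzchar(hdr$id %||% "")) hdr$id else NULL,
    native_id = hdr$native_id,
    retention_time_s = if (!is.null(hdr$retention_time_s)) as.numeric(hdr$retention_time_s) else NULL,
    fragmentation = hdr$fragmentation,
    normalize = TRUE
  )
}

#' Read spectra from any supported format
#'
#' Dispatches on the declared or detected format (`mgf`, `mzml`, `mzxml`).
#'
#' @param path Input file.
#' @param format Format name, or `"auto"` to detect from the extension.
#' @return List of [spectrum()] objects.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml", "mzxml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mgf = "mgf", mzml = "mzml", mzxml = "mzxml",
                     stop("cannot detect spectra format of '", path, "'",
                          call. = FALSE))
  }
  switch(format, mgf = read_mgf(path), mzml = read_mzml(path),
         mzxml = read_mzxml(path))
}
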