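# Consensus prediction across tools. Each input document is treated as one
# tool's output; spectra are matched across documents by native id / title,
# then scan index, then precursor m/z, and the top-ranked candidate
# sequences are grouped into equivalence classes. A class supported by at
# least `min_agreement` tools becomes one consensus prediction, itself a
# valid DNMSO document entry.

#' Consensus parameters
#'
#' @param min_agreement Minimum number of tools that must agree (>= 2).
#' @param equivalence `"strict"` (element-kind equality) or
#'   `"IL_equivalent"` (leucine and isoleucine collapse — they are isobaric
#'   and indistinguishable from fragment masses).
#' @param gap_tolerance_da A gap element matches a residue run whose summed
#'   residue mass is within this many Daltons (default 0.01).
#' @param max_rank Compare candidates up to this rank per tool (default 1 =
#'   top-ranked only).
#' @return A `dnmso_consensus_params`.
#' @export
consensus_params <- function(min_agreement = 2L,
                             equivalence = c("strict", "IL_equivalent"),
                             gap_tolerance_da = 0.01, max_rank = 1L) {
  equivalence <- match.arg(equivalence)
  min_agreement <- as.integer(min_agreement)
  if (is.na(min_agreement) || min_agreement < 2L) {
    stop("min_agreement must be an integer >= 2", call. = FALSE)
  }
  structure(list(min_agreement = min_agreement, equivalence = equivalence,
                 gap_tolerance_da = gap_tolerance_da,
                 max_rank = as.integer(max_rank)),
            class = "dnmso_consensus_params")
}

canon_residue <- function(res, il) if (il && res %in% c("I", "L")) "J" else res

# Equivalence between two sequences, optionally collapsing I/L and letting a
# gap in one sequence absorb a residue run of matching summed mass in the
# other. Recursive two-pointer match; sequences are short.
sequences_equivalent <- function(a, b, equivalence = "strict",
                                 gap_tol = 0.01,
                                 mods_a = list(), mods_b = list()) {
  il <- identical(equivalence, "IL_equivalent")
  ea <- a$elements; eb <- b$elements
  el_mass <- function(el, mods) {
    switch(el$kind,
           aa = residue_mono_mass(el$residue),
           gap = el$mass,
           mod_aa = {
             m <- mods[[el$modification_ref]]
             residue_mono_mass(el$residue) + if (is.null(m)) 0 else m$mono_mass_delta
           })
  }
  same_el <- function(x, y) {
    if (x$kind != y$kind) return(FALSE)
    if (x$kind == "gap") return(abs(x$mass - y$mass) <= gap_tol)
    if (!identical(canon_residue(x$residue, il), canon_residue(y$residue, il))) return(FALSE)
    if (x$kind == "mod_aa") {
      ma <- mods_a[[x$modification_ref]]; mb <- mods_b[[y$modification_ref]]
      acc_a <- if (is.null(ma)) x$modification_ref else ma$psimod_accession
      acc_b <- if (is.null(mb)) y$modification_ref else mb$psimod_accession
      return(identical(acc_a, acc_b))
    }
    TRUE
  }
  rec <- function(i, j) {
    if (i > length(ea) && j > length(eb)) return(TRUE)
    if (i > length(ea) || j > length(eb)) return(FALSE)
    x <- ea[[i]]; y <- eb[[j]]
    if (same_el(x, y) && rec(i + 1L, j + 1L)) return(TRUE)
    # a gap may absorb a run of non-gap elements of matching summed mass
    if (x$kind == "gap") {
      acc <- 0
      k <- j
      while (k <= length(eb) && eb[[k]]$kind != "gap") {
        acc <- acc + el_mass(eb[[k]], mods_b)
        k <- k + 1L
        if (acc > x$mass + gap_tol) break
        if (abs(acc - x$mass) <= gap_tol && rec(i + 1L, k)) return(TRUE)
      }
    }
    if (y$kind == "gap") {
      acc <- 0
      k <- i
      while (k <= length(ea) && ea[[k]]$kind != "gap") {
        acc <- acc + el_mass(ea[[k]], mods_a)
        k <- k + 1L
        if (acc > y$mass + gap_tol) break
        if (abs(acc - y$mass) <= gap_tol && rec(k, j + 1L)) return(TRUE)
      }
    }
    FALSE
  }
  rec(1L, 1L)
}

spectrum_match_key <- function(s, index) {
  list(title = s$native_id %||% s$id, index = index, mz = s$precursor_mz)
}

# Match spectra across documents: native id / title exact match first, then
# scan index, then precursor m/z within 0.01 Th; first match wins.
match_spectrum <- function(key, doc) {
  ids <- names(doc$spectra)
  for (k in seq_along(ids)) {
    s <- doc$spectra[[k]]
    if (identical(s$native_id %||% s$id, key$title)) return(ids[k])
  }
  if (!is.null(key$index) && key$index >= 1 && key$index <= length(ids)) {
    return(ids[key$index])
  }
  if (!is.na(key$mz)) {
    for (k in seq_along(ids)) {
      smz <- doc$spectra[[k]]$precursor_mz
      if (!is.na(smz) && abs(smz - key$mz) <= 0.01) return(ids[k])
    }
  }
  NULL
}

#' Consensus prediction across tool outputs
#'
#' Takes one document per tool, matches their spectra, compares each tool's
#' top-ranked candidate sequences under the chosen equivalence, and emits one
#' consensus prediction per spectrum whose largest agreement class reaches
#' `min_agreement`. Consensus predictions carry the scores
#' `agreement_count` (class size) and `mean_normalized_rank` (mean of
#' `1/rank` over the agreeing candidates) and are produced by the software
#' entry `"dnmso-consensus"`, so the output is again a valid document.
#'
#' @param docs List of at least two `dnmso_document` objects.
#' @param params A [consensus_params()].
#' @return A `dnmso_document` with the matched spectra and the consensus
#'   predictions; spectra present in only some inputs are skipped with a
#'   warning. The per-spectrum outcome is attached as
#'   `attr(out, "report")`, a tibble.
#' @export
consensus <- function(docs, params = consensus_params()) {
  if (!is.list(docs) || length(docs) < 2 ||
      !all(vapply(docs, inherits, logical(1), "dnmso_document"))) {
    stop("consensus needs a list of >= 2 documents", call. = FALSE)
  }
  stopifnot(inherits(params, "dnmso_consensus_params"))
  out <- dnmso_document(creator = "dnmso-consensus")
  out <- add_software(out, software("dnmso-consensus",
                                    version = as.character(utils::packageVersion("dnmso"))))
  report <- list()
  anchor <- docs[[1]]
  anchor_ids <- names(anchor$spectra)
  for (k in seq_along(anchor_ids)) {
    key <- spectrum_match_key(anchor$spectra[[k]], k)
    matched_ids <- vector("list", length(docs))
    matched_ids[[1]] <- anchor_ids[k]
    ok <- TRUE
    for (t in seq_along(docs)[-1]) {
      m <- match_spectrum(key, docs[[t]])
      if (is.null(m)) { ok <- FALSE; break }
      matched_ids[[t]] <- m
    }
    if (!ok) {
      warning("spectrum '", key$title, "' not matched in all inputs; skipped",
              call. = FALSE)
      report[[length(report) + 1L]] <- tibble::tibble(
        spectrum = key$title, status = "unmatched", agreement = NA_integer_)
      next
    }
    # candidates: (tool, prediction) pairs up to max_rank per tool
    cands <- list()
    for (t in seq_along(docs)) {
      preds <- predictions_for_spectrum(docs[[t]], matched_ids[[t]])
      for (p in preds) {
        rk <- p$rank %||% 1L
        if (rk <= params$max_rank) {
          cands[[length(cands) + 1L]] <- list(tool = t, pred = p,
                                              mods = docs[[t]]$modifications)
        }
      }
    }
    if (length(cands) == 0) {
      report[[length(report) + 1L]] <- tibble::tibble(
        spectrum = key$title, status = "no_candidates", agreement = 0L)
      next
    }
    classes <- equivalence_classes(cands, params)
    sizes <- vapply(classes, function(cl) length(unique(vapply(cl, function(c) c$tool, integer(1)))), integer(1))
    best <- which.max(sizes)
    spec_out <- anchor$spectra[[k]]
    out_spec_id <- spec_out$id
    if (sizes[best] >= params$min_agreement) {
      cl <- classes[[best]]
      if (is.null(out$spectra[[out_spec_id]])) out <- add_spectrum(out, spec_out)
      rep_cand <- cl[[1]]
      # consensus document must resolve the representative's modifications
      for (el in rep_cand$pred$sequence$elements) {
        if (el$kind == "mod_aa") {
          m <- rep_cand$mods[[el$modification_ref]]
          if (!is.null(m) && is.null(out$modifications[[m$local_id]])) {
            out <- add_modification(out, m)
          }
        }
      }
      ranks <- vapply(cl, function(c) as.numeric(c$pred$rank %||% 1L), numeric(1))
      out <- add_prediction(out, prediction(
        sequence = rep_cand$pred$sequence,
        scores = list(score("agreement_count", sizes[best]),
                      score("mean_normalized_rank", mean(1 / ranks))),
        source_spectrum_refs = out_spec_id,
        software_ref = "dnmso-consensus", rank = 1L))
      report[[length(report) + 1L]] <- tibble::tibble(
        spectrum = key$title, status = "consensus", agreement = sizes[best])
    } else {
      report[[length(report) + 1L]] <- tibble::tibble(
        spectrum = key$title, status = "no_agreement", agreement = sizes[best])
    }
  }
  attr(out, "report") <- dplyr::bind_rows(report)
  out
}

# Union-find over candidates under pairwise sequence equivalence.
equivalence_classes <- function(cands, params) {
  n <- length(cands)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (find(i) == find(j)) next
      if (sequences_equivalent(cands[[i]]$pred$sequence, cands[[j]]$pred$sequence,
                               equivalence = params$equivalence,
                               gap_tol = params$gap_tolerance_da,
                               mods_a = cands[[i]]$mods, mods_b = cands[[j]]$mods)) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(seq_len(n), roots), function(idx) cands[idx]))
}
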