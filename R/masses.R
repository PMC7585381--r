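# Monoisotopic residue masses for the 20 standard amino acids, computed from
# elemental compositions (e.g. Gly = C2H3NO). Non-standard residues (U, O) are
# deliberately rejected.

AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Mass of a water molecule (monoisotopic, Da)
#' @export
MASS_WATER <- 18.010565

#' Mass of a proton (Da)
#' @export
MASS_PROTON <- 1.007276

#' Monoisotopic residue mass of a standard amino acid
#'
#' Returns the monoisotopic mass of the amino-acid *residue* (the in-chain
#' form, i.e. the free amino acid minus one water), in Daltons.
#'
#' @param residue One or more single uppercase letters from the 20-letter
#'   standard amino-acid alphabet.
#' @return Numeric vector of residue masses in Daltons.
#' @examples
#' residue_mono_mass("G")
#' residue_mono_mass(c("P", "E", "P"))
#' @export
residue_mono_mass <- function(residue) {
  if (length(residue) == 0) return(numeric(0))
  if (!is.character(residue) || any(is.na(residue)) || any(nchar(residue) != 1)) {
    stop("alphabet error: residues must be single letters", call. = FALSE)
  }
  bad <- setdiff(unique(residue), names(AA_MONO))
  if (length(bad) > 0) {
    stop("alphabet error: unknown residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(AA_MONO[residue])
}

#' Neutral monoisotopic mass implied by a precursor m/z and charge
#'
#' @param mz Precursor mass-to-charge ratio in Thomson.
#' @param charge Positive integer charge state.
#' @return Neutral mass in Daltons: `(mz - proton) * charge`.
#' @export
precursor_neutral_mass <- function(mz, charge) {
  stopifnot(is.numeric(mz), is.numeric(charge), charge >= 1)
  (mz - MASS_PROTON) * charge
}
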