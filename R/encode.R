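# Canonical residue -> column mapping: the 20 one-letter codes in
# alphabetical order. This ordering is part of the model serialization
# contract and must not change.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The 24-residue CLIP segment of the invariant chain (Ii 81-104)
#'
#' Class II-associated invariant chain peptide, a naturally promiscuous
#' binder used as a standard probe of register identification across
#' allotypes.
#' @export
CLIP <- "LPKPPKPVSKMRMATPLLMQALPM"

.splitSeq <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

# Integer encoding (columns of the one-hot matrix); errors name the first
# offending position.
.encodeIdx <- function(sequence, minLength = 9L) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  chars <- .splitSeq(toupper(sequence))
  if (length(chars) < minLength)
    stop(sprintf("peptide of length %d is shorter than the minimum %d",
                 length(chars), minLength))
  idx <- match(chars, AA_CODES)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf(
      "non-canonical residue '%s' at position %d; allowed alphabet: %s",
      chars[bad], bad, paste(AA_CODES, collapse = "")))
  }
  idx
}

#' One-hot encode a peptide sequence
#'
#' Maps a peptide to an L x 20 binary matrix with exactly one 1 per row.
#' Columns follow the 20 canonical one-letter amino-acid codes in
#' alphabetical order (ACDEFGHIKLMNPQRSTVWY); this mapping is fixed.
#'
#' @param sequence character string over the canonical 20-letter alphabet,
#'   length >= 9.
#' @return L x 20 integer matrix, column names the amino-acid codes.
#' @examples
#' encodePeptide("ACDEFGHIK")
#' @export
encodePeptide <- function(sequence) {
  idx <- .encodeIdx(sequence)
  m <- matrix(0L, nrow = length(idx), ncol = 20L,
              dimnames = list(NULL, AA_CODES))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Convert between IC50 and binding affinity
#'
#' Affinities are free energies of binding on a scale where larger values
#' mean stronger binding: dG = -RT ln(IC50 in molar), so IC50 = 1 M maps to
#' dG = 0 and IC50 = 1 nM to about 12.3 kcal/mol at RT = 0.592. This sign
#' convention is required for the Boltzmann average, which upweights
#' strongly binding registers via exp(+dG/kT).
#'
#' @param ic50 positive IC50 values in nM.
#' @param dG affinities in kcal/mol.
#' @param RT gas constant times temperature, kcal/mol (default 0.592,
#'   T = 298 K).
#' @return \code{ic50ToAffinity}: affinities in kcal/mol;
#'   \code{affinityToIC50}: IC50 in nM. The two are exact inverses.
#' @examples
#' ic50ToAffinity(1000)           # 0.592 * log(1e6) ~ 8.18 kcal/mol
#' affinityToIC50(ic50ToAffinity(50))
#' @export
ic50ToAffinity <- function(ic50, RT = 0.592) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 values must be positive and finite")
  -RT * log(ic50 * 1e-9)
}

#' @rdname ic50ToAffinity
#' @export
affinityToIC50 <- function(dG, RT = 0.592) {
  exp(-dG / RT) * 1e9
}
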