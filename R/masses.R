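# Standard monoisotopic residue masses (Da) and Kyte-Doolittle hydropathy.

#' Monoisotopic residue masses
#'
#' Named numeric vector of standard monoisotopic residue masses in Dalton for
#' the 20 canonical amino acids (residue = amino acid minus one water).
#'
#' @format Named numeric vector of length 20.
#' @export
MONO_RESIDUE_MASSES <- c(
  A =  71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G =  57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P =  97.052764, S =  87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V =  99.068414
)

# monoisotopic mass of one water molecule (Da), added once per peptide
WATER_MONO <- 18.010565

# Kyte-Doolittle hydropathy indices, used by the detectability heuristic
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Regular expression matching any non-canonical residue letter
#' @noRd
NON_CANONICAL_RE <- "[^ACDEFGHIKLMNPQRSTVWY]"

#' Monoisotopic peptide mass
#'
#' Computes the uncharged, unmodified monoisotopic mass of peptides as the
#' sum of standard residue masses plus one water (18.010565 Da).
#'
#' @param sequences Character vector of peptide sequences (canonical residues
#'   only, uppercase).
#' @return Numeric vector of masses in Dalton.
#' @examples
#' peptide_mass(c("G", "AG"))
#' @export
peptide_mass <- function(sequences) {
  if (length(sequences) == 0L) return(numeric(0))
  if (any(is.na(sequences)) || any(!nzchar(sequences)))
    stop("peptide_mass(): empty or missing peptide sequence")
  chars <- strsplit(paste(sequences, collapse = ""), "", fixed = TRUE)[[1]]
  m <- MONO_RESIDUE_MASSES[chars]
  if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    stop("peptide_mass(): non-canonical residue(s): ",
         paste(bad, collapse = ", "))
  }
  ends <- cumsum(nchar(sequences))
  cs <- c(0, cumsum(m))
  unname(cs[ends + 1L] - cs[ends - nchar(sequences) + 1L]) + WATER_MONO
}

#' Mean Kyte-Doolittle hydropathy (GRAVY) of peptides
#'
#' @param sequences Character vector of peptide sequences.  Non-canonical
#'   letters are ignored in the average.
#' @return Numeric vector of GRAVY values.
#' @export
gravy <- function(sequences) {
  vapply(strsplit(sequences, "", fixed = TRUE), function(ch) {
    h <- KD_HYDROPATHY[ch]
    h <- h[!is.na(h)]
    if (length(h) == 0L) return(0)
    mean(h)
  }, numeric(1))
}
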