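# Synthetic proteome generator: reproducible FASTA databases with a
# controlled small/large protein composition, used as test inputs and in
# the worked examples.

#' Average residue frequencies used by the synthetic generator
#'
#' Approximate bacterial proteome amino-acid composition; every catalogued
#' protease has recognition sites (K, R, E, D, F, W, Y, L all present).
#'
#' @format Named numeric vector over the 20 canonical residues (sums to 1).
#' @export
BACTERIAL_AA_FREQS <- local({
  f <- c(L = 0.100, A = 0.089, G = 0.072, V = 0.070, I = 0.060, E = 0.060,
         S = 0.058, K = 0.058, R = 0.055, D = 0.054, T = 0.054, P = 0.047,
         N = 0.043, Q = 0.039, F = 0.039, Y = 0.032, M = 0.024, H = 0.021,
         C = 0.012, W = 0.011)
  f / sum(f)
})

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` random protein sequences: an exact
#' `round_half_up(small_fraction * n_proteins)` of them with lengths
#' uniform in `small_range` (small proteins, <= 70 residues by default) and
#' the rest uniform in `large_range`.  Residues are sampled independently
#' from `residue_freqs`.  Headers carry the true length group
#' (`group=small|large`) so tests can assert against it.  The same seed
#' reproduces the identical proteome.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param small_fraction Fraction of small proteins in `[0, 1]`.
#' @param small_range,large_range Inclusive integer length ranges.
#' @param residue_freqs Named residue sampling frequencies.
#' @param seed Integer seed.
#' @return Tibble `protein_id`, `description`, `sequence`, `length`,
#'   `group` (the true generated group).
#' @export
generate_synthetic_proteome <- function(n_proteins = 1000,
                                        small_fraction = 0.3,
                                        small_range = c(15, 70),
                                        large_range = c(71, 450),
                                        residue_freqs = BACTERIAL_AA_FREQS,
                                        seed = 1) {
  stopifnot(n_proteins >= 1, small_fraction >= 0, small_fraction <= 1,
            small_range[1] >= 1, small_range[2] >= small_range[1],
            large_range[1] > 70 || small_fraction == 1,
            large_range[2] >= large_range[1])
  residue_freqs <- residue_freqs / sum(residue_freqs)
  set.seed(seed %% .Machine$integer.max)
  n_small <- round_half_up(small_fraction * n_proteins)
  lens <- c(
    if (n_small > 0)
      sample(small_range[1]:small_range[2], n_small, replace = TRUE),
    if (n_proteins - n_small > 0)
      sample(large_range[1]:large_range[2], n_proteins - n_small,
             replace = TRUE)
  )
  grp <- rep(c("small", "large"), c(n_small, n_proteins - n_small))
  letters_pool <- names(residue_freqs)
  all_chars <- sample(letters_pool, sum(lens), replace = TRUE,
                      prob = residue_freqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seqs <- vapply(seq_len(n_proteins), function(i)
    paste(all_chars[starts[i]:ends[i]], collapse = ""), character(1))
  ids <- sprintf("syn%04d", seq_len(n_proteins))
  tibble(
    protein_id = ids,
    description = sprintf("%s group=%s len=%d", ids, grp, lens),
    sequence = seqs,
    length = as.integer(lens),
    group = grp
  )
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with `protein_id`/`description` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- if ("description" %in% names(records))
    records$description else records$protein_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
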