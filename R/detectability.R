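# Peptide detectability: externally supplied scores, a documented heuristic,
# or the neutral uniform table.  Scores in [0, 1] multiply sampling weights.

new_detectability_table <- function(scores, source) {
  structure(list(scores = scores, source = source),
            class = "detectability_table")
}

#' Load per-peptide detectability scores from a TSV file
#'
#' Expects a tab-delimited file with header `peptide  score`, scores in
#' `[0, 1]`.  Scores typically come from an external predictor (any model
#' that maps a peptide sequence to a detection likelihood can be used).
#' Duplicated peptides must carry identical scores (within 1e-9).
#'
#' @param path Path to the TSV file.
#' @return A `detectability_table` (source `"file"`).
#' @export
load_detectability <- function(path) {
  if (!file.exists(path)) stop("detectability file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("detectability file is empty: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("peptide", "score")))
    stop("detectability file must have header 'peptide\\tscore'")
  if (length(lines) == 1L)
    return(new_detectability_table(setNames(numeric(0), character(0)),
                                   "file"))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("detectability file line ", bad[1] + 1L, ": expected 2 columns")
  pep <- vapply(parts, `[[`, character(1), 1L)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(sc))
    stop("detectability file line ", which(is.na(sc))[1] + 1L,
         ": non-numeric score")
  out_of_range <- which(sc < 0 | sc > 1)
  if (length(out_of_range))
    stop("detectability file line ", out_of_range[1] + 1L,
         ": score outside [0, 1] (", sc[out_of_range[1]], ")")
  if (anyDuplicated(pep)) {
    rng <- tapply(sc, pep, function(x) diff(range(x)))
    if (any(rng > 1e-9))
      stop("conflicting scores for duplicated peptide(s): ",
           paste(names(rng)[rng > 1e-9], collapse = ", "))
    keep <- !duplicated(pep)
    pep <- pep[keep]; sc <- sc[keep]
  }
  new_detectability_table(setNames(sc, pep), "file")
}

#' Uniform (neutral) detectability table
#'
#' Maps every peptide to score 1, i.e. sampling weights reduce to protein
#' abundance alone.
#'
#' @return A `detectability_table` (source `"uniform"`).
#' @export
uniform_detectability <- function() {
  new_detectability_table(NULL, "uniform")
}

#' Heuristic detectability table
#'
#' @return A `detectability_table` (source `"heuristic"`) that scores
#'   peptides with [heuristic_score()] at lookup time.
#' @export
heuristic_detectability <- function() {
  new_detectability_table(NULL, "heuristic")
}

#' Heuristic peptide detectability score
#'
#' A deterministic stand-in scoring function penalising peptide lengths and
#' hydropathies outside the well-detected range.  With peptide length `L`
#' and mean Kyte-Doolittle hydropathy `g` (GRAVY):
#'
#' \deqn{d_L = \max(0, \max(8 - L, L - 20)), \quad
#'       s = e^{-(d_L/10)^2} \cdot e^{-(\max(0,|g|-1)/1.5)^2}}
#'
#' so peptides of 8-20 residues with moderate hydropathy (`|g| <= 1`) score
#' 1, and the score decays smoothly towards the length extremes and for
#' strongly hydrophobic or hydrophilic sequences.
#'
#' @param peptides Character vector of peptide sequences.
#' @return Numeric vector of scores in `(0, 1]`.
#' @export
heuristic_score <- function(peptides) {
  L <- nchar(peptides)
  d_len <- pmax(0, pmax(8 - L, L - 20))
  g <- gravy(peptides)
  d_gravy <- pmax(0, abs(g) - 1)
  exp(-(d_len / 10)^2) * exp(-(d_gravy / 1.5)^2)
}

#' Look up detectability scores for peptides
#'
#' @param table A `detectability_table`.
#' @param peptides Character vector of peptide sequences.
#' @param fallback Score used for peptides absent from a file-backed table
#'   (default 1, neutral weight).
#' @param warn Warn once when fallback scores are used.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
lookup_detectability <- function(table, peptides, fallback = 1, warn = TRUE) {
  stopifnot(inherits(table, "detectability_table"))
  switch(table$source,
    uniform = rep.int(1, length(peptides)),
    heuristic = heuristic_score(peptides),
    file = {
      sc <- unname(table$scores[peptides])
      missing <- is.na(sc)
      if (any(missing)) {
        if (warn)
          warning(sum(missing), " peptide(s) absent from detectability ",
                  "table; using fallback score ", fallback)
        sc[missing] <- fallback
      }
      sc
    },
    stop("unknown detectability source: ", table$source))
}

#' Combine abundance and detectability into a sampling weight
#'
#' @param abundance Non-negative protein abundance.
#' @param detectability Score in `[0, 1]`.
#' @param enabled If `FALSE`, detectability is ignored and the weight is
#'   the abundance alone.
#' @return Numeric sampling weight.
#' @export
combine_weight <- function(abundance, detectability, enabled = TRUE) {
  stopifnot(all(abundance >= 0))
  if (enabled) abundance * detectability else abundance
}
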