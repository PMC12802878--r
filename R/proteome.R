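# Proteome loading, length grouping and virtual-sample construction.

#' Load a protein database from FASTA
#'
#' Reads a (possibly multi-line) FASTA protein database.  The protein
#' identifier is the first whitespace-delimited token of the header; the full
#' header is retained as `description`.  Sequences are uppercased; residue
#' letters outside the 20 canonical amino acids are retained here (peptides
#' containing them are discarded later, at digestion).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `description`, `sequence`,
#'   `length`, in file order.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    stop("FASTA file contains no entries: ", path)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate protein identifier(s) in FASTA: ",
         paste(dup, collapse = ", "))
  }
  sequence <- toupper(as.character(seqs))
  empty <- !nzchar(sequence)
  if (any(empty))
    stop("empty sequence for FASTA entry: ",
         paste(ids[empty], collapse = ", "))
  tibble(
    protein_id = unname(ids),
    description = unname(headers),
    sequence = unname(sequence),
    length = nchar(sequence)
  )
}

#' Define protein length groups
#'
#' Length groups must partition `[1, Inf)`: intervals are inclusive, sorted,
#' gap-free and overlap-free, and the last interval must be unbounded.
#' The default reflects the small-protein focus: proteins of at most 70
#' amino acids form the `small` group, everything longer is `large`.
#'
#' @param labels Character vector of group labels.
#' @param min_length,max_length Integer vectors of inclusive bounds
#'   (`max_length` may be `Inf` for the last group).
#' @return A tibble with columns `label`, `min_length`, `max_length`.
#' @examples
#' group_definitions()  # small [1,70], large [71,Inf)
#' @export
group_definitions <- function(labels = c("small", "large"),
                              min_length = c(1, 71),
                              max_length = c(70, Inf)) {
  g <- tibble(label = as.character(labels),
              min_length = as.numeric(min_length),
              max_length = as.numeric(max_length))
  validate_groups(g)
  g
}

validate_groups <- function(groups) {
  stopifnot(all(c("label", "min_length", "max_length") %in% names(groups)))
  if (anyDuplicated(groups$label))
    stop("duplicate group labels")
  o <- order(groups$min_length)
  g <- groups[o, ]
  if (g$min_length[1] != 1)
    stop("group intervals must start at length 1")
  if (any(g$max_length < g$min_length))
    stop("group interval with max_length < min_length")
  if (nrow(g) > 1) {
    gaps <- g$min_length[-1] != g$max_length[-nrow(g)] + 1
    if (any(gaps))
      stop("group intervals must partition [1, Inf): gap or overlap at ",
           paste(g$label[-1][gaps], collapse = ", "))
  }
  if (is.finite(g$max_length[nrow(g)]))
    stop("last group interval must be unbounded (max_length = Inf)")
  invisible(groups)
}

#' Assign proteins to length groups
#'
#' @param records Protein tibble from [load_fasta()].
#' @param groups Group definition tibble from [group_definitions()].
#' @return `records` with a `group` column.
#' @export
assign_groups <- function(records, groups = group_definitions()) {
  validate_groups(groups)
  o <- order(groups$min_length)
  idx <- findInterval(records$length, groups$min_length[o])
  records$group <- groups$label[o][idx]
  records
}

#' Abundance model for virtual samples
#'
#' Protein abundances stand in for relative copy numbers.  Draws come from a
#' log-normal distribution (default location 0, log-scale SD 2, spanning
#' roughly four orders of magnitude as in bacterial cells); a fixed fraction
#' of each group is set absent (abundance 0) per virtual sample.  The zeroed
#' count is exact: `round_half_up(fraction * group size)` proteins per group,
#' chosen uniformly at random.
#'
#' @param distribution Only `"lognormal"` is currently implemented.
#' @param location Mean of log-abundance.
#' @param scale Standard deviation of log-abundance (> 0).
#' @param undetectable_fraction Either a single fraction in `[0, 1]` applied
#'   to every group, or a named numeric vector with one fraction per group
#'   label.
#' @return An object of class `abundance_model`.
#' @export
abundance_model <- function(distribution = "lognormal", location = 0,
                            scale = 2, undetectable_fraction = 0.45) {
  if (!identical(distribution, "lognormal"))
    stop("unsupported abundance distribution: ", distribution)
  if (!is.numeric(scale) || scale <= 0)
    stop("abundance scale must be > 0")
  if (any(undetectable_fraction < 0) || any(undetectable_fraction > 1))
    stop("undetectable_fraction must be in [0, 1]")
  structure(list(distribution = distribution, location = location,
                 scale = scale,
                 undetectable_fraction = undetectable_fraction),
            class = "abundance_model")
}

# round-half-up on non-negative values (avoids R's round-half-even)
round_half_up <- function(x) floor(x + 0.5)

group_fraction <- function(model, label) {
  f <- model$undetectable_fraction
  if (length(f) == 1L && is.null(names(f))) return(unname(f))
  if (!label %in% names(f))
    stop("no undetectable_fraction configured for group '", label, "'")
  unname(f[[label]])
}

#' Build one virtual sample of protein abundances
#'
#' Per group, exactly `round_half_up(fraction * group size)` proteins are set
#' absent (abundance 0, chosen uniformly at random); the remaining proteins
#' receive independent log-normal draws.  The per-sample seed is
#' `master_seed + sample_index`, so each replicate is independently
#' reproducible.
#'
#' @param records Grouped protein tibble (needs `protein_id`, `group`).
#' @param model An [abundance_model()].
#' @param sample_index Zero-based replicate index.
#' @param master_seed Integer master seed.
#' @return Named numeric vector of abundances, one per protein, in record
#'   order.
#' @export
sample_abundances <- function(records, model, sample_index, master_seed) {
  stopifnot(inherits(model, "abundance_model"), sample_index >= 0)
  set.seed((master_seed + sample_index) %% .Machine$integer.max)
  ab <- setNames(numeric(nrow(records)), records$protein_id)
  for (label in unique(records$group)) {
    idx <- which(records$group == label)
    n <- length(idx)
    n_zero <- round_half_up(group_fraction(model, label) * n)
    zero_idx <- if (n_zero > 0) sample(idx, n_zero) else integer(0)
    live_idx <- setdiff(idx, zero_idx)
    ab[live_idx] <- rlnorm(length(live_idx), meanlog = model$location,
                           sdlog = model$scale)
  }
  ab
}

#' Build all virtual samples for a run
#'
#' @inheritParams sample_abundances
#' @param n_samples Number of Monte-Carlo replicates.
#' @return Numeric matrix (proteins x samples); column `s<i>` holds sample
#'   `i` (zero-based).
#' @export
build_virtual_samples <- function(records, model, n_samples, master_seed) {
  stopifnot(n_samples >= 1)
  ab <- vapply(seq_len(n_samples) - 1L, function(i)
    sample_abundances(records, model, i, master_seed),
    numeric(nrow(records)))
  ab <- matrix(ab, nrow = nrow(records),
               dimnames = list(records$protein_id,
                               paste0("s", seq_len(n_samples) - 1L)))
  ab
}

#' Write / read the editable preparation table
#'
#' The preparation table is a UTF-8 TSV with header
#' `protein_id  length  group  abundance_s0  abundance_s1 ...`, one row per
#' protein.  Users may edit the `group` column (e.g. to regroup proteins by
#' localisation) or replace abundances with experimental values; edits are
#' honoured by the analysis stage.
#'
#' @param records Grouped protein tibble.
#' @param abundances Matrix from [build_virtual_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prep_table <- function(records, abundances, path) {
  stopifnot(nrow(records) == nrow(abundances))
  ns <- ncol(abundances)
  header <- c("protein_id", "length", "group",
              paste0("abundance_s", seq_len(ns) - 1L))
  num <- apply(abundances, 2L, function(x) sprintf("%.15g", x))
  if (nrow(records) == 1L) num <- matrix(num, nrow = 1L)
  rows <- apply(cbind(records$protein_id, records$length, records$group, num),
                1L, paste, collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), rows), con)
  invisible(path)
}

#' @rdname write_prep_table
#' @return `read_prep_table()` returns a list with `records` (tibble
#'   `protein_id`, `length`, `group`) and `abundances` (proteins x samples
#'   matrix).
#' @export
read_prep_table <- function(path) {
  if (!file.exists(path)) stop("prep table not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("prep table is empty: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  fixed <- c("protein_id", "length", "group")
  if (!identical(header[1:3], fixed))
    stop("prep table must start with columns protein_id, length, group")
  ab_cols <- header[-(1:3)]
  if (length(ab_cols) == 0L)
    stop("prep table has no abundance columns")
  expected <- paste0("abundance_s", seq_along(ab_cols) - 1L)
  if (!identical(ab_cols, expected))
    stop("unknown or misordered prep-table columns: ",
         paste(setdiff(ab_cols, expected), collapse = ", "))
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad_n <- which(lengths(parts) != length(header))
  if (length(bad_n))
    stop("prep table line ", bad_n[1] + 1L, ": expected ",
         length(header), " columns, found ", lengths(parts)[bad_n[1]])
  m <- do.call(rbind, parts)
  ab <- suppressWarnings(
    matrix(as.numeric(m[, -(1:3), drop = FALSE]), nrow = nrow(m)))
  bad <- which(apply(is.na(ab), 1L, any))
  if (length(bad))
    stop("prep table line ", bad[1] + 1L,
         ": non-numeric abundance value (protein ", m[bad[1], 1], ")")
  if (any(ab < 0))
    stop("prep table contains negative abundance values")
  len <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(len))
    stop("prep table line ", which(is.na(len))[1] + 1L,
         ": non-integer length")
  dimnames(ab) <- list(m[, 1], paste0("s", seq_len(ncol(ab)) - 1L))
  list(
    records = tibble(protein_id = m[, 1], length = len, group = m[, 3]),
    abundances = ab
  )
}
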