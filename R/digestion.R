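# In-silico digestion: cleavage-site enumeration, missed-cleavage peptide
# generation, mass/length filtering and peptide-to-proteome substring mapping.

#' Internal cleavage boundaries of a sequence
#'
#' A boundary `b` means the protease may cut between residues `b` and `b + 1`
#' (1-based residues), i.e. `b` residues lie before the cut.  For a
#' C-terminal cutter a cut after residue `b` requires residue `b` to be a
#' recognised residue and residue `b + 1` not to be in `blocked_next`; for an
#' N-terminal cutter a cut before residue `b + 1` requires residue `b + 1`
#' to be recognised.  Protein termini are never boundaries.
#'
#' @param sequence Single protein sequence.
#' @param protease A [protease_spec()].
#' @return Sorted integer vector of boundaries in `1 .. nchar(sequence) - 1`.
#' @examples
#' cat_ <- protease_catalogue()
#' cleavage_sites("MKTAYIAKQR", cat_$trypsin_p)   # 2, 8
#' cleavage_sites("MKTAYIAKQR", cat_$lysarginase) # 1, 7, 9
#' @export
cleavage_sites <- function(sequence, protease) {
  stopifnot(inherits(protease, "protease_spec"), nzchar(sequence))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2L) return(integer(0))
  if (protease$side == "C") {
    b <- which(ch %in% protease$residues)
    b <- b[b < n]
    if (length(protease$blocked_next))
      b <- b[!ch[b + 1L] %in% protease$blocked_next]
  } else {
    b <- which(ch %in% protease$residues) - 1L
    b <- b[b >= 1L]
  }
  sort(b)
}

#' Digest one sequence into peptides with missed cleavages
#'
#' With `c` internal boundaries, the `c + 1` fragments between consecutive
#' boundaries (including the termini) are the fully cleaved (0-MC) peptides;
#' a peptide with exactly `m` missed cleavages is the concatenation of
#' `m + 1` consecutive fragments.
#'
#' @inheritParams cleavage_sites
#' @param max_mc Maximal number of missed cleavages (defaults to the length
#'   of the protease's `mc_fractions` minus one).
#' @return Tibble with columns `sequence`, `mc_count`, `start`, `end`
#'   (1-based inclusive positions within the input sequence).
#' @export
digest_sequence <- function(sequence, protease, max_mc = protease$max_mc) {
  stopifnot(max_mc >= 0)
  b <- cleavage_sites(sequence, protease)
  pos <- c(0L, b, nchar(sequence))
  nfrag <- length(pos) - 1L
  ms <- 0:min(max_mc, nfrag - 1L)
  starts <- integer(0); ends <- integer(0); mc <- integer(0)
  for (m in ms) {
    i <- seq_len(nfrag - m)
    starts <- c(starts, pos[i] + 1L)
    ends <- c(ends, pos[i + m + 1L])
    mc <- c(mc, rep.int(m, length(i)))
  }
  tibble(sequence = substring(sequence, starts, ends),
         mc_count = mc, start = starts, end = ends)
}

#' Digest a whole proteome with one protease
#'
#' @param records Protein tibble (needs `protein_id`, `sequence`).
#' @inheritParams digest_sequence
#' @return Tibble `protein_id`, `sequence` (peptide), `mc_count`, `start`,
#'   `end`.
#' @export
digest_proteome <- function(records, protease, max_mc = protease$max_mc) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    d <- digest_sequence(records$sequence[i], protease, max_mc)
    d$protein_id <- records$protein_id[i]
    d
  })
  bind_rows(out)[, c("protein_id", "sequence", "mc_count", "start", "end")]
}

#' Peptide detection-window filter
#'
#' Inclusive length and monoisotopic-mass bounds for detectable peptides.
#' Defaults (6-45 residues, 400-6000 Da) describe a typical bottom-up
#' detection window.
#'
#' @param min_length,max_length Residue-count bounds.
#' @param min_mass,max_mass Mass bounds in Dalton.
#' @return An object of class `peptide_filter`.
#' @export
peptide_filter <- function(min_length = 6, max_length = 45,
                           min_mass = 400, max_mass = 6000) {
  if (min_length > max_length || min_mass > max_mass)
    stop("peptide_filter(): min must not exceed max")
  structure(list(min_length = min_length, max_length = max_length,
                 min_mass = min_mass, max_mass = max_mass),
            class = "peptide_filter")
}

#' Apply a detection-window filter to a peptide table
#'
#' Bounds are inclusive on both sides.  The table must carry `sequence` and
#' `mass_da` columns.
#'
#' @param peptides Peptide tibble.
#' @param filter A [peptide_filter()].
#' @return Filtered tibble.
#' @export
filter_peptides <- function(peptides, filter = peptide_filter()) {
  stopifnot(inherits(filter, "peptide_filter"))
  len <- nchar(peptides$sequence)
  keep <- len >= filter$min_length & len <= filter$max_length &
    peptides$mass_da >= filter$min_mass & peptides$mass_da <= filter$max_mass
  peptides[keep, , drop = FALSE]
}

# Build a k-mer position index over the concatenated proteome; reused across
# proteases so the text is scanned once.
kmer_index <- function(records, k) {
  concat <- paste(records$sequence, collapse = "-")
  prot_start <- cumsum(c(1L, head(nchar(records$sequence), -1L) + 1L))
  n <- nchar(concat)
  if (n < k) {
    index <- split(integer(0), character(0))
  } else {
    starts <- seq_len(n - k + 1L)
    index <- split(starts, substring(concat, starts, starts + k - 1L))
  }
  list(concat = concat, prot_start = prot_start, index = index, k = k,
       protein_id = records$protein_id)
}

#' Map peptide sequences to a proteome as plain substrings
#'
#' Finds every exact occurrence of each peptide sequence in the protein
#' database, including overlapping occurrences within one protein and
#' irrespective of the cleavage rule that generated the peptide.  Mapping by
#' sequence alone (not by cleavage specificity) matters because semi-specific
#' cleavage products can otherwise masquerade as unique peptides.
#'
#' @param peptides Character vector of peptide sequences (need not be
#'   unique; each distinct sequence is mapped once).
#' @param records Protein tibble (`protein_id`, `sequence`).
#' @return Tibble `peptide`, `protein_id`, `start`, `end` (1-based
#'   inclusive), one row per occurrence, ordered by peptide then protein
#'   then position.  Peptides with no occurrence yield no rows.
#' @export
map_peptides <- function(peptides, records) {
  peps <- unique(peptides)
  if (length(peps) == 0L)
    return(tibble(peptide = character(0), protein_id = character(0),
                  start = integer(0), end = integer(0)))
  k <- min(6L, min(nchar(peps)))
  ki <- kmer_index(records, k)
  pref <- substr(peps, 1L, k)
  cand <- ki$index[pref]
  cand[vapply(cand, is.null, logical(1))] <- list(integer(0))
  cnt <- lengths(cand)
  pep_i <- rep.int(seq_along(peps), cnt)
  pos <- unlist(cand, use.names = FALSE)
  if (length(pos)) {
    L <- nchar(peps)[pep_i]
    ok <- substring(ki$concat, pos, pos + L - 1L) == peps[pep_i]
    pep_i <- pep_i[ok]; pos <- pos[ok]; L <- L[ok]
  } else {
    L <- integer(0)
  }
  prot_i <- findInterval(pos, ki$prot_start)
  out <- tibble(peptide = peps[pep_i],
                protein_id = ki$protein_id[prot_i],
                start = pos - ki$prot_start[prot_i] + 1L,
                end = pos - ki$prot_start[prot_i] + L)
  out[order(match(out$peptide, peps), match(out$protein_id,
                                            ki$protein_id), out$start), ]
}

#' Build the combined annotated peptide table
#'
#' Runs digestion, the detection-window filter, substring mapping and the
#' uniqueness filter for each protease, and combines the results.  One row
#' per (peptide sequence, protease, occurrence); an identical sequence
#' produced by two proteases appears once per protease, mirroring an
#' experimental design where each digest is measured separately.  Peptides
#' containing non-canonical residue letters are discarded with a logged
#' count.  If a sequence arises from the same protease with several MC
#' counts, the smallest is recorded.
#'
#' @param records Protein tibble from [load_fasta()] (or the synthetic
#'   generator).
#' @param proteases Protease names or `protease_spec` list
#'   (see [resolve_proteases()]).
#' @param filter A [peptide_filter()].
#' @param require_unique Keep only peptides mapping to exactly one position
#'   in the whole database (default `TRUE`).
#' @param detectability Optional detectability table
#'   (see [load_detectability()]) used to fill the `detectability` column;
#'   `NULL` leaves it `NA`.
#' @param max_mc Optional cap on missed cleavages (defaults to each
#'   protease's own `mc_fractions` length minus one).
#' @return Tibble with columns `peptide`, `protease`, `mc_count`, `mass_da`,
#'   `protein_id`, `start_1based`, `end_1based`, `n_occurrences`,
#'   `is_unique`, `detectability`, ordered by protease, protein, position.
#' @export
build_peptide_table <- function(records, proteases,
                                filter = peptide_filter(),
                                require_unique = TRUE,
                                detectability = NULL,
                                max_mc = NULL) {
  specs <- resolve_proteases(proteases)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    dig <- digest_proteome(records, sp,
                           if (is.null(max_mc)) sp$max_mc else max_mc)
    # peptide-level view: distinct sequence, smallest MC count
    dig <- dig[order(dig$sequence, dig$mc_count), ]
    pep <- dig[!duplicated(dig$sequence), c("sequence", "mc_count")]
    bad <- grepl(NON_CANONICAL_RE, pep$sequence)
    if (any(bad))
      message(sp$name, ": discarded ", sum(bad),
              " peptide(s) with non-canonical residues")
    pep <- pep[!bad, , drop = FALSE]
    pep$mass_da <- peptide_mass(pep$sequence)
    pep <- filter_peptides(pep, filter)
    occ <- map_peptides(pep$sequence, records)
    nocc <- table(occ$peptide)
    occ$n_occurrences <- as.integer(nocc[occ$peptide])
    occ$is_unique <- occ$n_occurrences == 1L
    if (require_unique) occ <- occ[occ$is_unique, , drop = FALSE]
    m <- match(occ$peptide, pep$sequence)
    out[[i]] <- tibble(
      peptide = occ$peptide,
      protease = sp$name,
      mc_count = pep$mc_count[m],
      mass_da = pep$mass_da[m],
      protein_id = occ$protein_id,
      start_1based = occ$start,
      end_1based = occ$end,
      n_occurrences = occ$n_occurrences,
      is_unique = occ$is_unique
    )
  }
  tbl <- bind_rows(out)
  tbl <- tbl[order(match(tbl$protease, names(specs)),
                   match(tbl$protein_id, records$protein_id),
                   tbl$start_1based, tbl$peptide), ]
  tbl$detectability <- if (is.null(detectability)) {
    NA_real_
  } else {
    lookup_detectability(detectability, tbl$peptide, warn = FALSE)
  }
  tbl
}

#' Write / read the combined peptide table
#'
#' Tab-delimited serialisation of [build_peptide_table()] output; positions
#' are 1-based inclusive.
#'
#' @param peptides Peptide tibble.
#' @param path File path.
#' @return `path` invisibly; `read_peptide_table()` returns the tibble.
#' @export
write_peptide_table <- function(peptides, path) {
  readr::write_tsv(peptides, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_peptide_table
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  tbl <- readr::read_tsv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      peptide = readr::col_character(),
      protease = readr::col_character(),
      mc_count = readr::col_integer(),
      mass_da = readr::col_double(),
      protein_id = readr::col_character(),
      start_1based = readr::col_integer(),
      end_1based = readr::col_integer(),
      n_occurrences = readr::col_integer(),
      is_unique = readr::col_logical(),
      detectability = readr::col_double()
    ))
  need <- c("peptide", "protease", "mc_count", "mass_da", "protein_id",
            "start_1based", "end_1based", "n_occurrences", "is_unique",
            "detectability")
  if (!all(need %in% names(tbl)))
    stop("peptide table is missing column(s): ",
         paste(setdiff(need, names(tbl)), collapse = ", "))
  tbl[, need]
}
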