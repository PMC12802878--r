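# Independent brute-force oracles: deliberately naive per-position /
# sliding-window implementations used to validate the package's digestion
# and mapping code on small inputs.

oracle_sites <- function(sequence, protease) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  b <- integer(0)
  if (n < 2L) return(b)
  for (i in 1:(n - 1L)) {
    cut <- if (protease$side == "C") {
      (ch[i] %in% protease$residues) &&
        !(ch[i + 1L] %in% protease$blocked_next)
    } else {
      ch[i + 1L] %in% protease$residues
    }
    if (cut) b <- c(b, i)
  }
  b
}

oracle_digest <- function(sequence, protease, max_mc) {
  pos <- c(0L, oracle_sites(sequence, protease), nchar(sequence))
  np <- length(pos)
  starts <- integer(0); ends <- integer(0); mcs <- integer(0)
  for (i in 1:(np - 1L)) {
    for (j in (i + 1L):np) {
      m <- j - i - 1L
      if (m > max_mc) break
      starts <- c(starts, pos[i] + 1L)
      ends <- c(ends, pos[j])
      mcs <- c(mcs, m)
    }
  }
  data.frame(sequence = substring(sequence, starts, ends),
             mc_count = mcs, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# naive sliding-window substring scan over every protein
oracle_map <- function(peptides, records) {
  out <- list()
  for (pep in unique(peptides)) {
    L <- nchar(pep)
    for (r in seq_len(nrow(records))) {
      s <- records$sequence[r]
      n <- nchar(s)
      if (n < L) next
      for (i in 1:(n - L + 1L)) {
        if (substr(s, i, i + L - 1L) == pep)
          out[[length(out) + 1L]] <- data.frame(
            peptide = pep, protein_id = records$protein_id[r],
            start = i, end = i + L - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(peptide = character(0), protein_id = character(0),
                      start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(proteasim::BACTERIAL_AA_FREQS), len, replace = TRUE,
               prob = proteasim::BACTERIAL_AA_FREQS), collapse = "")
}

digestion_key <- function(d) {
  sort(paste(d$sequence, d$mc_count, d$start, sep = "|"))
}

write_tmp_fasta <- function(text) {
  path <- tempfile(fileext = ".fasta")
  writeLines(text, path)
  path
}
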