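# Monte-Carlo core: missed-cleavage bin allocation, weighted sampling
# without replacement, protein inference and the per-sample simulation loop.

#' Allocate a sampling total across missed-cleavage bins
#'
#' Distributes `total` sampled peptide identifications over MC bins in
#' proportion to the protease's expected MC fractions, using
#' largest-remainder rounding so the allocation sums exactly to `total`
#' (ties broken towards lower MC counts).  Bins whose peptide pool is empty
#' are reallocated proportionally to the remaining bins' fractions.
#'
#' @param total Non-negative integer total to allocate.
#' @param mc_fractions Numeric fractions over MC counts `0..max_mc`
#'   (sum to 1).
#' @param pool_sizes Optional integer vector of available (positive-weight)
#'   pool sizes per bin; bins with `pool_sizes == 0` receive nothing.
#' @return Integer vector of the same length as `mc_fractions`, summing to
#'   `total`.
#' @examples
#' allocate_mc_bins(10000, c(0.95, 0.05))  # 9500, 500
#' @export
allocate_mc_bins <- function(total, mc_fractions, pool_sizes = NULL) {
  stopifnot(length(total) == 1L, total >= 0)
  total <- as.integer(total)
  f <- as.numeric(mc_fractions)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("mc_fractions must be non-negative and sum to 1")
  nb <- length(f)
  if (is.null(pool_sizes)) pool_sizes <- rep.int(Inf, nb)
  stopifnot(length(pool_sizes) == nb)
  open <- pool_sizes > 0
  if (!any(open)) {
    if (total == 0L) return(integer(nb))
    stop("all missed-cleavage peptide pools are empty")
  }
  if (any(!open & f > 0))
    message("reallocating fraction ", format(sum(f[!open])),
            " from empty MC bin(s) ",
            paste(which(!open & f > 0) - 1L, collapse = ", "),
            " to remaining bins")
  g <- ifelse(open, f, 0)
  if (sum(g) == 0) g <- as.numeric(open)  # degenerate: spread equally
  g <- g / sum(g)
  q <- total * g
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- q - base
    take <- order(-frac, seq_len(nb))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Weighted sampling without replacement
#'
#' Draws `n` distinct items with probability proportional to `weights`
#' among the remaining candidates at each draw (implemented via
#' exponential-key sorting, which is distributionally equivalent to
#' sequential weighted draws).  Zero-weight items are never drawn.  If fewer
#' than `n` positive-weight items exist, all of them are returned and the
#' shortfall is logged.
#'
#' @param weights Non-negative numeric weights.
#' @param n Number of draws.
#' @param replace Sample with replacement instead (sensitivity analysis).
#' @param seed Optional seed set before drawing; with a fixed seed the draw
#'   is reproducible.
#' @return Integer vector of selected indices.
#' @export
weighted_sample <- function(weights, n, replace = FALSE, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("n must be >= 0")
  n <- as.integer(n)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  pos <- which(weights > 0)
  if (n == 0L || length(pos) == 0L) {
    if (n > 0L) message("weighted_sample: no positive-weight items; ",
                        "shortfall of ", n)
    return(integer(0))
  }
  if (replace)
    return(pos[sample.int(length(pos), n, replace = TRUE,
                          prob = weights[pos])])
  if (length(pos) <= n) {
    if (length(pos) < n)
      message("weighted_sample: only ", length(pos),
              " positive-weight items for ", n, " draws")
    return(pos)
  }
  keys <- rexp(length(pos)) / weights[pos]
  pos[order(keys)[seq_len(n)]]
}

# fraction of each protein's residues covered by the union of the given
# peptide intervals; returns a named numeric vector over proteins present
coverage_by_protein <- function(occ, protein_lengths) {
  if (nrow(occ) == 0L) return(setNames(numeric(0), character(0)))
  rng <- IRanges::IRanges(start = occ$start_1based, end = occ$end_1based)
  rl <- IRanges::reduce(S4Vectors::split(rng, occ$protein_id))
  covered <- sum(IRanges::width(rl))
  covered / protein_lengths[names(covered)]
}

#' Infer identified proteins from sampled peptides
#'
#' In unique-peptide mode (the default workflow) a protein is identified
#' when at least `min_unique` distinct sampled unique peptide sequences map
#' to it; per-protein sequence coverage is the covered fraction of the
#' protein (union of the sampled peptides' residue intervals).  With
#' `min_unique = 2` this is the classical two-unique-peptides rule.
#'
#' In shared-peptide mode (`shared_mode = TRUE`, for runs with the
#' uniqueness filter off) proteins sharing exactly the same set of sampled
#' peptide sequences are merged into protein groups; a group is identified
#' when its shared peptide set holds at least `min_unique` distinct
#' sequences, and its peptide count and coverage are the medians over
#' member proteins.  A group's length-group label is the most frequent
#' label among members (ties broken by database order).
#'
#' @param sampled Occurrence-level tibble of sampled peptides with columns
#'   `peptide`, `protein_id`, `start_1based`, `end_1based` (and `protease`
#'   when several digests are pooled).
#' @param records Protein tibble with `protein_id`, `length`, `group`.
#' @param min_unique Minimal number of distinct peptides (1 or 2).
#' @param shared_mode Protein-group mode, see above.
#' @return List with `proteins` (tibble `protein_id`, `group`,
#'   `n_peptides`, `coverage`; one row per identified protein or protein
#'   group) and `by_group` (tibble `group`, `n_prot`, `n_pep`, `mean_cov`,
#'   one row per length group in `records`).
#' @export
infer_proteins <- function(sampled, records, min_unique = 1,
                           shared_mode = FALSE) {
  stopifnot(min_unique >= 1)
  labels <- unique(records$group)
  lens <- setNames(as.numeric(records$length), records$protein_id)
  gmap <- setNames(records$group, records$protein_id)
  if (shared_mode)
    return(.infer_shared(sampled, records, min_unique, labels, lens, gmap))
  # distinct sampled sequences per protein
  dp <- unique(sampled[, c("peptide", "protein_id")])
  npep_seq <- table(dp$protein_id)
  ids <- names(npep_seq)[npep_seq >= min_unique]
  rows_id <- sampled[sampled$protein_id %in% ids, , drop = FALSE]
  cov <- coverage_by_protein(rows_id, lens)
  proteins <- tibble(
    protein_id = ids,
    group = unname(gmap[ids]),
    n_peptides = as.integer(tabulate(factor(rows_id$protein_id,
                                            levels = ids),
                                     nbins = length(ids))),
    coverage = unname(cov[ids])
  )
  list(proteins = proteins,
       by_group = .group_rollup(proteins, labels))
}

.group_rollup <- function(proteins, labels) {
  out <- lapply(labels, function(lb) {
    p <- proteins[proteins$group == lb, , drop = FALSE]
    tibble(group = lb, n_prot = nrow(p),
           n_pep = sum(p$n_peptides),
           mean_cov = if (nrow(p)) mean(p$coverage) else 0)
  })
  bind_rows(out)
}

.infer_shared <- function(sampled, records, min_unique, labels, lens, gmap) {
  occ <- unique(sampled[, intersect(c("peptide", "protease", "protein_id",
                                      "start_1based", "end_1based"),
                                    names(sampled))])
  pep_sets <- lapply(split(occ$peptide, occ$protein_id),
                     function(x) sort(unique(x)))
  prot_ids <- names(pep_sets)
  sig <- vapply(pep_sets, paste, character(1), collapse = "\r")
  # keep database order so tie-breaks are deterministic
  prot_order <- match(prot_ids, records$protein_id)
  o <- order(prot_order)
  prot_ids <- prot_ids[o]; sig <- sig[o]; pep_sets <- pep_sets[o]
  grp_of <- match(sig, unique(sig))
  n_seq <- lengths(pep_sets)
  cov <- coverage_by_protein(occ, lens)
  # per-protein count of sampled (peptide, protease) pairs
  key_cols <- intersect(c("peptide", "protease"), names(occ))
  pk <- unique(occ[, c(key_cols, "protein_id")])
  n_keys <- table(pk$protein_id)
  groups <- unique(grp_of)
  rows <- lapply(groups, function(g) {
    members <- prot_ids[grp_of == g]
    if (n_seq[[match(members[1], prot_ids)]] < min_unique) return(NULL)
    lbl <- gmap[members]
    lab <- names(sort(table(lbl), decreasing = TRUE))[1]
    tibble(protein_id = paste(members, collapse = ";"),
           group = lab,
           n_peptides = as.integer(round(median(
             as.integer(n_keys[members])))),
           coverage = median(unname(cov[members])))
  })
  proteins <- bind_rows(rows)
  if (is.null(proteins) || nrow(proteins) == 0L)
    proteins <- tibble(protein_id = character(0), group = character(0),
                       n_peptides = integer(0), coverage = numeric(0))
  list(proteins = proteins, by_group = .group_rollup(proteins, labels))
}

# deterministic sub-seed per (sample, protease), independent of which other
# proteases are part of the run
.name_hash <- function(s) {
  v <- utf8ToInt(s)
  sum(v * seq_along(v)) %% 100003L
}

derive_seed <- function(master_seed, sample_index, protease_name) {
  as.integer((as.numeric(master_seed) + 1009 * (sample_index + 1) +
                31 * .name_hash(protease_name)) %% 2147483647)
}

# draw one protease's identified peptides for one virtual sample
.sample_protease <- function(plev, occ, spec, abund, total,
                             detectability_enabled, with_replacement,
                             seed) {
  det <- if (detectability_enabled) {
    d <- plev$detectability
    d[is.na(d)] <- 1
    d
  } else rep.int(1, nrow(plev))
  ab_occ <- abund[occ$protein_id]
  w_by_pep <- rowsum(ab_occ, occ$peptide)
  w <- unname(w_by_pep[plev$peptide, 1L]) * det
  set.seed(seed)
  nb <- length(spec$mc_fractions)
  # peptides with more MCs than the model covers are not part of any pool
  bin_of <- ifelse(plev$mc_count < nb, plev$mc_count + 1L, NA_integer_)
  pool_sizes <- vapply(seq_len(nb), function(b)
    sum(!is.na(bin_of) & bin_of == b & w > 0), integer(1))
  alloc <- allocate_mc_bins(total, spec$mc_fractions, pool_sizes)
  picked <- integer(0)
  for (b in seq_len(nb)) {
    if (alloc[b] == 0L) next
    idx <- which(!is.na(bin_of) & bin_of == b)
    sel <- weighted_sample(w[idx], alloc[b], replace = with_replacement)
    picked <- c(picked, idx[sel])
  }
  plev$peptide[picked]
}

#' Run the full Monte-Carlo simulation
#'
#' For every virtual sample and every protease, sampling weights are
#' assembled (protein abundance, optionally multiplied by peptide
#' detectability), the requested identification count is allocated across
#' missed-cleavage bins, peptides are drawn without replacement with
#' weight-proportional probability, and identified proteins are inferred
#' under both the 1-unique and 2-unique peptide rules.  Combination results
#' take, within the same virtual sample, the union of the member proteases'
#' identified-protein sets, the summed sampled peptides of those proteins,
#' and the coverage of the pooled peptide intervals, mirroring separately
#' measured digests of one sample.
#'
#' @param peptides Peptide table from [build_peptide_table()] (or
#'   [read_peptide_table()]).
#' @param prep List with `records` (tibble `protein_id`, `length`, `group`)
#'   and `abundances` (proteins x samples matrix), as returned by
#'   [read_prep_table()].
#' @param proteases Protease names or specs; must cover the peptide table.
#' @param peptides_per_protease Single count or named vector: peptides
#'   designated as identified per protease and sample (default 10000).
#' @param combinations List of character vectors of protease names; default
#'   all non-empty subsets up to `max_k`.
#' @param max_k Maximal combination size (default: all proteases).
#' @param detectability_enabled Multiply weights by the peptide table's
#'   `detectability` column (missing scores fall back to 1).
#' @param with_replacement Sample with replacement (default `FALSE`).
#' @param shared_mode Protein-group inference for tables built with the
#'   uniqueness filter off; default: enabled automatically when the table
#'   contains non-unique peptides.
#' @param master_seed Integer master seed; per-(sample, protease) sub-seeds
#'   are derived deterministically from it.
#' @return Tibble of per-round results: `sample_index`, `combination`
#'   (member names joined by `+`), `group`, `rule` (`"1-unique"` /
#'   `"2-unique"`), `n_prot`, `n_pep`, `mean_cov`.
#' @export
run_monte_carlo <- function(peptides, prep, proteases,
                            peptides_per_protease = 10000,
                            combinations = NULL, max_k = NULL,
                            detectability_enabled = FALSE,
                            with_replacement = FALSE,
                            shared_mode = NULL,
                            master_seed = 1) {
  specs <- resolve_proteases(proteases)
  pnames <- names(specs)
  if (is.null(shared_mode)) shared_mode <- any(!peptides$is_unique)
  totals <- if (length(peptides_per_protease) == 1L &&
                is.null(names(peptides_per_protease))) {
    setNames(rep.int(as.integer(peptides_per_protease), length(pnames)),
             pnames)
  } else {
    missing <- setdiff(pnames, names(peptides_per_protease))
    if (length(missing))
      stop("peptides_per_protease missing for: ",
           paste(missing, collapse = ", "))
    vapply(pnames, function(p)
      as.integer(peptides_per_protease[[p]]), integer(1))
  }
  if (any(totals < 1)) stop("peptides_per_protease must be >= 1")
  records <- prep$records
  ab <- prep$abundances
  if (!all(rownames(ab) == records$protein_id))
    ab <- ab[records$protein_id, , drop = FALSE]
  n_samples <- ncol(ab)
  if (is.null(combinations)) {
    if (is.null(max_k)) max_k <- length(pnames)
    combinations <- enumerate_combinations(pnames, max_k)
  }
  unknown <- setdiff(unique(unlist(combinations)), pnames)
  if (length(unknown))
    stop("combination refers to unknown protease(s): ",
         paste(unknown, collapse = ", "))
  labels <- unique(records$group)
  # per-protease pools
  pools <- lapply(pnames, function(nm) {
    sub <- peptides[peptides$protease == nm, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("peptide table has no peptides for protease '", nm, "'")
    bad <- setdiff(unique(sub$protein_id), records$protein_id)
    if (length(bad))
      stop("peptide table protein(s) absent from prep table: ",
           paste(head(bad, 3), collapse = ", "))
    plev <- sub[!duplicated(sub$peptide),
                c("peptide", "mc_count", "detectability")]
    list(plev = plev, occ = sub)
  })
  names(pools) <- pnames
  rounds <- vector("list", n_samples * length(combinations) * 2L)
  ri <- 0L
  for (s in seq_len(n_samples) - 1L) {
    abund <- ab[, s + 1L]
    per_prot <- lapply(pnames, function(nm) {
      po <- pools[[nm]]
      picked <- .sample_protease(
        po$plev, po$occ, specs[[nm]], abund, totals[[nm]],
        detectability_enabled, with_replacement,
        derive_seed(master_seed, s, nm))
      occ <- po$occ[po$occ$peptide %in% picked, , drop = FALSE]
      if (!shared_mode) {
        dp <- unique(occ[, c("peptide", "protein_id")])
        np <- table(dp$protein_id)
        list(occ = occ,
             ids1 = names(np)[np >= 1L],
             ids2 = names(np)[np >= 2L])
      } else {
        list(occ = occ)
      }
    })
    names(per_prot) <- pnames
    for (cb in combinations) {
      combo_label <- paste(cb, collapse = "+")
      all_occ <- bind_rows(lapply(per_prot[cb], `[[`, "occ"))
      if (shared_mode) {
        for (rule_i in 1:2) {
          inf <- infer_proteins(all_occ, records, min_unique = rule_i,
                                shared_mode = TRUE)
          bg <- inf$by_group
          bg$sample_index <- s
          bg$combination <- combo_label
          bg$rule <- paste0(rule_i, "-unique")
          ri <- ri + 1L
          rounds[[ri]] <- bg
        }
      } else {
        ids1 <- unique(unlist(lapply(per_prot[cb], `[[`, "ids1")))
        ids2 <- unique(unlist(lapply(per_prot[cb], `[[`, "ids2")))
        lens <- setNames(as.numeric(records$length), records$protein_id)
        gmap <- setNames(records$group, records$protein_id)
        rows1 <- all_occ[all_occ$protein_id %in% ids1, , drop = FALSE]
        cov <- coverage_by_protein(rows1, lens)
        for (rule_i in 1:2) {
          ids <- if (rule_i == 1L) ids1 else ids2
          rows_id <- rows1[rows1$protein_id %in% ids, , drop = FALSE]
          proteins <- tibble(
            protein_id = ids,
            group = unname(gmap[ids]),
            n_peptides = as.integer(
              tabulate(factor(rows_id$protein_id, levels = ids),
                       nbins = length(ids))),
            coverage = unname(cov[ids]))
          bg <- .group_rollup(proteins, labels)
          bg$sample_index <- s
          bg$combination <- combo_label
          bg$rule <- paste0(rule_i, "-unique")
          ri <- ri + 1L
          rounds[[ri]] <- bg
        }
      }
    }
  }
  out <- bind_rows(rounds[seq_len(ri)])
  out[, c("sample_index", "combination", "group", "rule",
          "n_prot", "n_pep", "mean_cov")]
}
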