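# Cleavage rules, missed-cleavage enumeration, masses, filtering and
# substring mapping.

cat_ <- protease_catalogue()

test_that("cleavage boundaries follow the C-/N-terminal rules", {
  expect_equal(cleavage_sites("MKTAYIAKQR", cat_$trypsin_p), c(2L, 8L))
  expect_equal(cleavage_sites("AKPGR", cat_$trypsin), integer(0))
  expect_equal(cleavage_sites("MKTAYIAKQR", cat_$lysarginase), c(1L, 7L, 9L))
  # terminal residues never yield boundaries
  expect_equal(cleavage_sites("K", cat_$trypsin), integer(0))
  expect_equal(cleavage_sites("KA", cat_$lysarginase), integer(0))
})

test_that("digestion enumerates missed-cleavage peptides exactly", {
  d0 <- digest_sequence("MKTAYIAKQR", cat_$trypsin_p, 0)
  expect_setequal(d0$sequence, c("MK", "TAYIAK", "QR"))
  expect_true(all(d0$mc_count == 0))

  d1 <- digest_sequence("MKTAYIAKQR", cat_$trypsin_p, 1)
  expect_setequal(d1$sequence[d1$mc_count == 1],
                  c("MKTAYIAK", "TAYIAKQR"))

  # no cleavage site: the whole sequence, 0 MC
  dn <- digest_sequence("AAAA", cat_$trypsin, 3)
  expect_equal(dn$sequence, "AAAA")
  expect_equal(dn$mc_count, 0L)
})

test_that("digestion equals brute-force enumeration on random sequences", {
  set.seed(31)
  specs <- cat_[c("trypsin", "chymotrypsin", "glu_c", "lysarginase",
                  "asp_n")]
  for (rep_i in 1:40) {
    s <- random_protein(sample(10:200, 1))
    for (sp in specs) {
      mine <- digest_sequence(s, sp, 5)
      ref <- oracle_digest(s, sp, 5)
      expect_identical(digestion_key(mine), digestion_key(ref))
      # counting law: c internal sites -> c + 1 - m peptides with m MCs
      cc <- length(cleavage_sites(s, sp))
      for (m in 0:min(cc, 5))
        expect_equal(sum(mine$mc_count == m), cc + 1L - m)
      # fragment conservation: 0-MC fragments re-assemble the protein
      frag <- mine[mine$mc_count == 0, ]
      expect_equal(paste(frag$sequence[order(frag$start)], collapse = ""), s)
    }
  }
})

test_that("C-terminal digestion mirrors N-terminal digestion of the reverse", {
  rev_str <- function(x)
    vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE)
  c_rule <- protease_spec("c_rule", c("K", "R"), "C")
  n_rule <- protease_spec("n_rule", c("K", "R"), "N")
  set.seed(77)
  for (i in 1:10) {
    s <- random_protein(sample(20:120, 1))
    a <- sort(digest_sequence(s, c_rule, 2)$sequence)
    b <- sort(rev_str(digest_sequence(rev_str(s), n_rule, 2)$sequence))
    expect_identical(a, b)
  }
})

test_that("monoisotopic masses are additive residue sums plus water", {
  expect_equal(peptide_mass("G"), 75.032028, tolerance = 1e-5)
  expect_equal(peptide_mass("AG"), 146.069142, tolerance = 1e-5)
  expect_error(peptide_mass(""), "empty")
  expect_error(peptide_mass("AXG"), "non-canonical")

  # mass additivity: mass(x + y) == mass(x) + mass(y) - water
  set.seed(5)
  for (i in 1:20) {
    x <- random_protein(sample(1:15, 1))
    y <- random_protein(sample(1:15, 1))
    expect_equal(peptide_mass(paste0(x, y)),
                 peptide_mass(x) + peptide_mass(y) - 18.010565,
                 tolerance = 1e-6)
  }
})

test_that("detection-window filter is inclusive on both bounds", {
  flt <- peptide_filter(min_length = 7, max_length = 30,
                        min_mass = 500, max_mass = 5000)
  tbl <- tibble::tibble(sequence = c("MK", "AAAAAAA", "G"),
                        mass_da = peptide_mass(c("MK", "AAAAAAA", "G")))
  kept <- filter_peptides(tbl, flt)
  expect_equal(kept$sequence, "AAAAAAA")  # exactly min_length, kept

  # mass bound excludes "G" even when length allows
  flt2 <- peptide_filter(min_length = 1, max_length = 30,
                         min_mass = 500, max_mass = 5000)
  expect_false("G" %in% filter_peptides(tbl, flt2)$sequence)
})

test_that("substring mapping finds every occurrence, including overlaps", {
  recs <- tibble::tibble(protein_id = c("p1", "p2"),
                         sequence = c("AAA", "TAYIAKQQ"))
  occ <- map_peptides(c("AA", "TAYIAK"), recs)
  aa <- occ[occ$peptide == "AA", ]
  expect_equal(nrow(aa), 2L)          # overlapping matches in "AAA"
  expect_equal(aa$start, c(1L, 2L))
  expect_equal(occ$start[occ$peptide == "TAYIAK"], 1L)
})

test_that("mapping equals the naive sliding-window oracle", {
  set.seed(91)
  recs <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:30),
    sequence = vapply(1:30, function(i) random_protein(sample(20:80, 1)),
                      character(1)))
  # include peptides that occur multiply: substrings of several proteins
  peps <- c(substring(recs$sequence[1], 1, 8),
            substring(recs$sequence[2], 5, 12),
            substring(recs$sequence[3], c(1, 3), c(6, 8)),
            "AA", "GL", "QWERTYNOTHERE")
  mine <- map_peptides(peps, recs)
  ref <- oracle_map(peps, recs)
  ref <- ref[order(match(ref$peptide, unique(peps)),
                   match(ref$protein_id, recs$protein_id), ref$start), ]
  expect_equal(nrow(mine), nrow(ref))
  expect_equal(paste(mine$peptide, mine$protein_id, mine$start, mine$end),
               paste(ref$peptide, ref$protein_id, ref$start, ref$end))
})

test_that("peptide table annotates per protease and drops non-unique", {
  recs <- tibble::tibble(
    protein_id = c("p1", "p2"),
    sequence = c("MMATYWDEKGGGGGGK", "LLNQSYIEKGGGGGGK"))
  tbl <- suppressMessages(build_peptide_table(
    recs, c("trypsin", "lys_c"),
    filter = peptide_filter(min_length = 6, max_length = 45,
                            min_mass = 1, max_mass = 10000)))
  # "GGGGGGK" (and MC variants) map twice -> excluded when unique required
  expect_false(any(!tbl$is_unique))
  expect_false("GGGGGGK" %in% tbl$peptide)
  # identical sequence from two proteases appears once per protease
  shared <- tbl[tbl$peptide == "MMATYWDEK", ]
  expect_setequal(shared$protease, c("trypsin", "lys_c"))

  # uniqueness off retains multi-mappers with their occurrence counts
  tbl_all <- suppressMessages(build_peptide_table(
    recs, "trypsin",
    filter = peptide_filter(6, 45, 1, 10000), require_unique = FALSE))
  gk <- tbl_all[tbl_all$peptide == "GGGGGGK", ]
  expect_equal(nrow(gk), 2L)
  expect_true(all(!gk$is_unique))
  expect_true(all(gk$n_occurrences == 2L))
  expect_gte(nrow(tbl_all), nrow(tbl[tbl$protease == "trypsin", ]))
})

test_that("peptides with non-canonical residues are discarded with a note", {
  recs <- tibble::tibble(protein_id = "p1",
                         sequence = "MMATYWDEKGXGGGGK")
  expect_message(
    tbl <- build_peptide_table(recs, "trypsin",
                               filter = peptide_filter(3, 45, 1, 10000)),
    "non-canonical")
  expect_false(any(grepl("X", tbl$peptide)))
})

test_that("peptide table serialisation round-trips deterministically", {
  recs <- tibble::tibble(protein_id = c("p1", "p2"),
                         sequence = c("MMATYWDEKGGGSSGK", "LLNQSYIEKAAAR"))
  tbl <- suppressMessages(build_peptide_table(
    recs, c("trypsin", "glu_c"), filter = peptide_filter(6, 45, 1, 10000)))
  path <- tempfile(fileext = ".tsv")
  write_peptide_table(tbl, path)
  back <- read_peptide_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  # rebuilt table is identical (deterministic row order)
  tbl2 <- suppressMessages(build_peptide_table(
    recs, c("trypsin", "glu_c"), filter = peptide_filter(6, 45, 1, 10000)))
  expect_identical(tbl, tbl2)
})
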