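# Proteome loading, length grouping, virtual samples and the prep table.

test_that("FASTA loading parses entries, ids and lengths", {
  path <- write_tmp_fasta(c(">p1", "MKTAYIAKQR", ">p2", "ACDEFG"))
  recs <- load_fasta(path)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$protein_id, c("p1", "p2"))
  expect_equal(recs$length, c(10L, 6L))

  # multi-line sequences are concatenated, lowercase is uppercased
  path2 <- write_tmp_fasta(c(">p1 desc", "mkta", "YIAK"))
  recs2 <- load_fasta(path2)
  expect_equal(recs2$sequence, "MKTAYIAK")

  # identifier is the first whitespace token; full header retained
  path3 <- write_tmp_fasta(c(">sp|P12345|NAME some description", "MK"))
  recs3 <- load_fasta(path3)
  expect_equal(recs3$protein_id, "sp|P12345|NAME")
  expect_match(recs3$description, "some description")
})

test_that("FASTA loading rejects missing files, duplicates and empties", {
  expect_error(load_fasta(file.path(tempdir(), "nope.fasta")), "nope.fasta")
  dup <- write_tmp_fasta(c(">p1", "MK", ">p1", "MK"))
  expect_error(load_fasta(dup), "duplicate")
  empty <- write_tmp_fasta(character(0))
  expect_error(load_fasta(empty), "no entries")
})

test_that("length groups partition [1, Inf) and label boundaries correctly", {
  g <- group_definitions()
  recs <- tibble::tibble(protein_id = c("a", "b", "c"),
                         length = c(70L, 71L, 1L))
  out <- assign_groups(recs, g)
  expect_equal(out$group, c("small", "large", "small"))

  # every length maps to exactly one group
  lens <- 1:1000
  lab <- assign_groups(tibble::tibble(protein_id = as.character(lens),
                                      length = lens), g)$group
  expect_true(all(lab %in% c("small", "large")))
  expect_equal(lab == "small", lens <= 70)

  one <- group_definitions("all", 1, Inf)
  expect_equal(unique(assign_groups(recs, one)$group), "all")

  expect_error(group_definitions(c("a", "b"), c(1, 70), c(70, Inf)),
               "gap|overlap")
  expect_error(group_definitions(c("a", "b"), c(1, 80), c(70, Inf)),
               "gap|overlap")
  expect_error(group_definitions("a", 1, 100), "unbounded")
})

test_that("virtual samples zero an exact per-group count", {
  recs <- tibble::tibble(protein_id = sprintf("p%04d", 1:1000),
                         length = rep(50L, 1000), group = "small")
  ab <- sample_abundances(recs, abundance_model(undetectable_fraction = 0.45),
                          0, 42)
  expect_equal(sum(ab == 0), 450L)
  expect_true(all(ab >= 0))

  all0 <- sample_abundances(recs, abundance_model(undetectable_fraction = 1),
                            0, 42)
  expect_true(all(all0 == 0))
  none0 <- sample_abundances(recs, abundance_model(undetectable_fraction = 0),
                             0, 42)
  expect_true(all(none0 > 0))

  # reproducible under identical (seed, sample_index)
  expect_identical(
    sample_abundances(recs, abundance_model(), 3, 42),
    sample_abundances(recs, abundance_model(), 3, 42))

  # per-group fractions and round-half-up counting
  recs2 <- tibble::tibble(protein_id = sprintf("q%03d", 1:25),
                          length = c(rep(50L, 5), rep(200L, 20)),
                          group = c(rep("small", 5), rep("large", 20)))
  m <- abundance_model(undetectable_fraction = c(small = 0.5, large = 0.1))
  ab2 <- sample_abundances(recs2, m, 0, 7)
  expect_equal(sum(ab2[recs2$group == "small"] == 0), 3L)  # half rounds up
  expect_equal(sum(ab2[recs2$group == "large"] == 0), 2L)
})

test_that("log-abundance draws match the configured location and scale", {
  recs <- tibble::tibble(protein_id = as.character(1:10000),
                         length = 100L, group = "all")
  ab <- sample_abundances(recs, abundance_model(location = 0, scale = 2,
                                                undetectable_fraction = 0),
                          0, 1234)
  lg <- log(ab)
  n <- length(lg)
  expect_lt(abs(mean(lg) - 0), 3 * 2 / sqrt(n))
  expect_lt(abs(sd(lg) - 2), 3 * 2 / sqrt(2 * n))
})

test_that("prep table round-trips and honours user edits", {
  recs <- tibble::tibble(protein_id = c("a", "b", "c"),
                         length = c(10L, 80L, 40L),
                         group = c("small", "large", "small"))
  ab <- matrix(c(1.5, 0, 3.25, 0.125, 2, 10),
               nrow = 3, dimnames = list(recs$protein_id, c("s0", "s1")))
  path <- tempfile(fileext = ".tsv")
  write_prep_table(recs, ab, path)
  back <- read_prep_table(path)
  expect_equal(back$records, recs)
  expect_equal(back$abundances, ab)

  # editing a group label is honoured on re-read
  lines <- readLines(path)
  lines[2] <- sub("\tsmall\t", "\tmembrane\t", lines[2])
  writeLines(lines, path)
  edited <- read_prep_table(path)
  expect_equal(edited$records$group[1], "membrane")

  # non-numeric abundance names the offending line
  lines[3] <- sub("\t0\t", "\tabc\t", lines[3])
  writeLines(lines, path)
  expect_error(read_prep_table(path), "line 3")

  # unknown columns are rejected
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tlength\tgroup\tbogus", "a\t10\tsmall\t1"), bad)
  expect_error(read_prep_table(bad), "bogus|misordered")
})

test_that("equal seeds give byte-identical prep tables", {
  recs <- assign_groups(tibble::tibble(
    protein_id = sprintf("p%02d", 1:20),
    length = c(rep(30L, 8), rep(150L, 12))))
  p1 <- tempfile(); p2 <- tempfile()
  write_prep_table(recs, build_virtual_samples(recs, abundance_model(),
                                               3, 99), p1)
  write_prep_table(recs, build_virtual_samples(recs, abundance_model(),
                                               3, 99), p2)
  expect_identical(readLines(p1), readLines(p2))
})
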