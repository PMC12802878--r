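# MC-bin allocation, weighted sampling, protein inference, and the
# Monte-Carlo loop.

test_that("MC-bin allocation uses largest-remainder rounding", {
  expect_equal(allocate_mc_bins(10000, c(0.95, 0.05)), c(9500L, 500L))
  expect_equal(allocate_mc_bins(10, 1), 10L)
  expect_equal(allocate_mc_bins(7, c(0.5, 0.3, 0.2)), c(4L, 2L, 1L))

  # allocation always conserves the total
  set.seed(21)
  for (i in 1:50) {
    nb <- sample(2:6, 1)
    f <- runif(nb); f <- f / sum(f)
    total <- sample(0:5000, 1)
    a <- allocate_mc_bins(total, f)
    expect_equal(sum(a), total)
    expect_true(all(a >= 0))
  }
})

test_that("empty pools are reallocated; fully empty pools error", {
  expect_message(
    a <- allocate_mc_bins(100, c(0.5, 0.3, 0.2), pool_sizes = c(10, 0, 10)),
    "reallocating")
  expect_equal(sum(a), 100L)
  expect_equal(a[2], 0L)
  # reallocation is proportional to the remaining fractions (0.5 : 0.2)
  expect_equal(a, c(71L, 0L, 29L))
  expect_error(allocate_mc_bins(10, c(0.5, 0.5), pool_sizes = c(0, 0)),
               "empty")
  expect_equal(allocate_mc_bins(0, c(0.5, 0.5), pool_sizes = c(0, 0)),
               c(0L, 0L))
})

test_that("weighted sampling respects weights, zeros and exhaustion", {
  w <- c(2, 0, 1, 5)
  # exhaustion returns exactly the positive-weight set
  expect_setequal(weighted_sample(w, 3, seed = 1), c(1L, 3L, 4L))
  expect_message(s <- weighted_sample(w, 10, seed = 1), "shortfall|only")
  expect_setequal(s, c(1L, 3L, 4L))
  expect_error(weighted_sample(w, -1), ">= 0")

  # zero-weight items are never drawn
  set.seed(42)
  draws <- replicate(2000, weighted_sample(c(1, 0, 1), 1))
  expect_false(any(draws == 2L))

  # single-draw frequencies follow the weights (chi-square)
  set.seed(99)
  w2 <- c(9, 1)
  draws <- replicate(5000, weighted_sample(w2, 1))
  counts <- tabulate(draws, nbins = 2)
  p <- suppressWarnings(stats::chisq.test(counts, p = w2 / sum(w2))$p.value)
  expect_gt(p, 0.001)

  # fixed seed reproduces the draw
  wbig <- runif(100)
  expect_identical(weighted_sample(wbig, 10, seed = 7),
                   weighted_sample(wbig, 10, seed = 7))
})

test_that("protein inference applies the unique-peptide thresholds", {
  records <- tibble::tibble(protein_id = c("A", "B"),
                            length = c(10L, 20L),
                            group = c("small", "large"))
  sampled <- tibble::tibble(
    peptide = c("PEPA", "PEPB", "PEPC"),
    protease = "trypsin",
    protein_id = c("A", "A", "B"),
    start_1based = c(1L, 3L, 1L),
    end_1based = c(2L, 8L, 20L))

  r2 <- infer_proteins(sampled, records, min_unique = 2)
  expect_equal(r2$proteins$protein_id, "A")
  # coverage: [1,2] u [3,8] = 8 of 10 residues
  expect_equal(r2$proteins$coverage, 0.8)

  r1 <- infer_proteins(sampled, records, min_unique = 1)
  expect_setequal(r1$proteins$protein_id, c("A", "B"))
  # full-length peptide gives coverage exactly 1
  expect_equal(r1$proteins$coverage[r1$proteins$protein_id == "B"], 1)
  # 2-unique identified set is a subset of the 1-unique set
  expect_true(all(r2$proteins$protein_id %in% r1$proteins$protein_id))
  # N_Pep counts only peptides of identified proteins
  expect_equal(r2$by_group$n_pep[r2$by_group$group == "small"], 2L)
  expect_equal(r2$by_group$n_prot[r2$by_group$group == "large"], 0L)
})

test_that("shared-peptide mode groups indistinguishable proteins", {
  records <- tibble::tibble(protein_id = c("A", "B", "C"),
                            length = c(10L, 12L, 30L),
                            group = c("small", "small", "large"))
  # A and B share both sampled peptides; C has its own
  sampled <- tibble::tibble(
    peptide = c("PP1", "PP1", "PP2", "PP2", "PP3"),
    protease = "trypsin",
    protein_id = c("A", "B", "A", "B", "C"),
    start_1based = c(1L, 1L, 5L, 5L, 1L),
    end_1based = c(4L, 4L, 10L, 10L, 15L))
  r <- infer_proteins(sampled, records, min_unique = 2, shared_mode = TRUE)
  expect_equal(nrow(r$proteins), 1L)
  expect_equal(r$proteins$protein_id, "A;B")
  # median of member coverages: A = 10/10, B = 10/12
  expect_equal(r$proteins$coverage, median(c(1, 10 / 12)))
  expect_equal(r$proteins$n_peptides, 2L)
  r1 <- infer_proteins(sampled, records, min_unique = 1, shared_mode = TRUE)
  expect_equal(nrow(r1$proteins), 2L)
})

test_that("Monte-Carlo runs are deterministic and union-monotonic", {
  syn <- generate_synthetic_proteome(80, 0.3, seed = 17)
  tbl <- suppressMessages(build_peptide_table(syn, c("trypsin", "glu_c")))
  prep <- list(records = syn[, c("protein_id", "length", "group")],
               abundances = build_virtual_samples(syn, abundance_model(),
                                                  3, 55))
  run1 <- suppressMessages(run_monte_carlo(
    tbl, prep, c("trypsin", "glu_c"), peptides_per_protease = 300,
    master_seed = 55))
  run2 <- suppressMessages(run_monte_carlo(
    tbl, prep, c("trypsin", "glu_c"), peptides_per_protease = 300,
    master_seed = 55))
  expect_identical(run1, run2)

  # sub-seeds do not depend on run composition: the trypsin-only run
  # reproduces the trypsin rows of the two-protease run
  solo <- suppressMessages(run_monte_carlo(
    tbl, prep, "trypsin", peptides_per_protease = 300, master_seed = 55))
  expect_equal(as.data.frame(solo[solo$combination == "trypsin", ]),
               as.data.frame(run1[run1$combination == "trypsin", ]))

  # combination results dominate every member protease (same sample)
  wide <- merge(
    run1[run1$combination == "trypsin+glu_c",
         c("sample_index", "group", "rule", "n_prot")],
    run1[run1$combination == "trypsin",
         c("sample_index", "group", "rule", "n_prot")],
    by = c("sample_index", "group", "rule"), suffixes = c("_combo", "_solo"))
  expect_true(all(wide$n_prot_combo >= wide$n_prot_solo))

  # 2-unique counts never exceed 1-unique counts
  w2 <- merge(
    run1[run1$rule == "1-unique",
         c("sample_index", "combination", "group", "n_prot")],
    run1[run1$rule == "2-unique",
         c("sample_index", "combination", "group", "n_prot")],
    by = c("sample_index", "combination", "group"),
    suffixes = c("_1", "_2"))
  expect_true(all(w2$n_prot_2 <= w2$n_prot_1))

  # coverage is a fraction in (0, 1] wherever proteins were identified
  cv <- run1$mean_cov[run1$n_prot > 0]
  expect_true(all(cv > 0 & cv <= 1))
})
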