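# The three pipeline stages (prepare / digest / analyze) plus the
# end-to-end runner and the command-line front end.  Stages communicate
# through editable TSV files, so each can be re-run independently and
# user edits (regrouping, experimental abundances) are honoured downstream.

.run_log <- function(cfg, dir, notes = character()) {
  lines <- c(
    paste0("proteasim ", as.character(packageVersion("proteasim"))),
    paste0("R ", R.version.string),
    paste0("seed: ", cfg$seed),
    paste0("proteases: ", paste(names(cfg$resolved$proteases),
                                collapse = ", ")),
    paste0("config: ", paste(deparse(cfg[setdiff(names(cfg), "resolved")]),
                             collapse = " ")),
    notes)
  writeLines(lines, file.path(dir, "run_log.txt"))
}

#' Prepare stage: grouped proteins and virtual samples
#'
#' Loads the FASTA database, assigns length groups, draws the configured
#' number of virtual samples and writes the editable preparation table to
#' `<output_dir>/prep_table.tsv`.
#'
#' @param cfg A validated [read_run_config()] object.
#' @return Invisible list with `records`, `abundances` and the table
#'   `path`.
#' @export
cmd_prepare <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir <- cfg$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  records <- load_fasta(cfg$fasta)
  records <- assign_groups(records, cfg$resolved$groups)
  ab <- build_virtual_samples(records, cfg$resolved$model, cfg$n_samples,
                              cfg$seed)
  path <- file.path(dir, "prep_table.tsv")
  write_prep_table(records, ab, path)
  .run_log(cfg, dir, paste0("prepared ", nrow(records), " proteins x ",
                            cfg$n_samples, " samples"))
  invisible(list(records = records, abundances = ab, path = path))
}

#' Digest stage: combined annotated peptide table
#'
#' Digests the FASTA database with every configured protease, applies the
#' detection-window and uniqueness filters, maps peptides back to the
#' proteome and writes `<output_dir>/peptide_table.tsv`.
#'
#' @param cfg A validated [read_run_config()] object.
#' @return Invisible list with the peptide `table` and its `path`.
#' @export
cmd_digest <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir <- cfg$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  records <- load_fasta(cfg$fasta)
  tbl <- build_peptide_table(
    records, cfg$resolved$proteases, filter = cfg$resolved$filter,
    require_unique = cfg$require_unique,
    detectability = cfg$resolved$detectability,
    max_mc = cfg$max_mc)
  path <- file.path(dir, "peptide_table.tsv")
  write_peptide_table(tbl, path)
  counts <- table(tbl$protease)
  message("peptides per protease: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  invisible(list(table = tbl, path = path))
}

#' Analyze stage: Monte-Carlo simulation and protease scores
#'
#' Reads the (possibly user-edited) preparation and peptide tables, runs
#' the Monte-Carlo simulation for every protease combination, scores each
#' round against the control workflow and writes `results.tsv` plus
#' `results_summary.tsv`.
#'
#' @param cfg A validated [read_run_config()] object.
#' @param prep_path,peptide_path Table paths; default to the files the
#'   earlier stages wrote into `output_dir`.
#' @return Invisible list with `rounds`, `scored`, `summary` tibbles and
#'   output `paths`.
#' @export
cmd_analyze <- function(cfg,
                        prep_path = file.path(cfg$output_dir,
                                              "prep_table.tsv"),
                        peptide_path = file.path(cfg$output_dir,
                                                 "peptide_table.tsv")) {
  stopifnot(inherits(cfg, "run_config"))
  prep <- read_prep_table(prep_path)
  peptides <- read_peptide_table(peptide_path)
  det_enabled <- !identical(cfg$resolved$detectability$source, "uniform")
  rounds <- run_monte_carlo(
    peptides, prep, cfg$resolved$proteases,
    peptides_per_protease = cfg$resolved$peptides_per_protease,
    max_k = cfg$max_k,
    detectability_enabled = det_enabled,
    with_replacement = isTRUE(cfg$with_replacement),
    shared_mode = if (cfg$require_unique) FALSE else TRUE,
    master_seed = cfg$seed)
  scored <- score_rounds(rounds, control = cfg$resolved$control,
                         weights = cfg$resolved$weights)
  paths <- write_score_tables(scored, cfg$output_dir)
  invisible(list(rounds = rounds, scored = scored,
                 summary = summarize_scores(scored), paths = paths))
}

#' Run the full pipeline
#'
#' [cmd_prepare()], [cmd_digest()] and [cmd_analyze()] in sequence.
#'
#' @param cfg A validated [read_run_config()] object.
#' @return Invisible list from [cmd_analyze()], plus the stage paths.
#' @export
run_pipeline <- function(cfg) {
  prep <- cmd_prepare(cfg)
  dig <- cmd_digest(cfg)
  res <- cmd_analyze(cfg)
  invisible(c(res, list(prep_path = prep$path, peptide_path = dig$path)))
}

# --- command-line front end -------------------------------------------------

.cli_usage <- function() {
  message(
    "usage: proteasim <command> --config FILE [--output-dir DIR]",
    " [--seed N] [--verbose]\n",
    "commands:\n",
    "  prepare       build the editable preparation table\n",
    "  digest        build the combined peptide table\n",
    "  analyze       Monte-Carlo simulation + protease scores\n",
    "  run           all three stages\n",
    "  make-fixture  write a synthetic proteome FASTA",
    " (--n, --small-fraction, --out)")
}

.cli_opts <- function(args) {
  opts <- list(config = NULL, output_dir = NULL, seed = NULL,
               verbose = FALSE, n = 200L, small_fraction = 0.3,
               out = "synthetic_proteome.fasta")
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    grab <- function() { i <<- i + 1L; if (i > length(args))
      stop("missing value for ", a); args[i] }
    switch(a,
      "--config" = { opts$config <- grab() },
      "--output-dir" = { opts$output_dir <- grab() },
      "--seed" = { opts$seed <- as.integer(grab()) },
      "--verbose" = { opts$verbose <- TRUE },
      "--n" = { opts$n <- as.integer(grab()) },
      "--small-fraction" = { opts$small_fraction <- as.numeric(grab()) },
      "--out" = { opts$out <- grab() },
      stop("unknown option: ", a))
    i <- i + 1L
  }
  opts
}

#' Command-line entry point
#'
#' Thin front end used by the installed `exec/proteasim` script.  Commands:
#' `prepare`, `digest`, `analyze`, `run`, `make-fixture`.  `--seed` and
#' `--output-dir` override the configuration file.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { .cli_usage(); return(invisible(1L)) }
  command <- args[1]
  status <- tryCatch({
    opts <- .cli_opts(args[-1])
    if (command == "make-fixture") {
      recs <- generate_synthetic_proteome(
        n_proteins = opts$n, small_fraction = opts$small_fraction,
        seed = opts$seed %||% 1L)
      write_fasta(recs, opts$out)
      message("wrote ", opts$out, " (", nrow(recs), " proteins)")
      return(invisible(0L))
    }
    if (!command %in% c("prepare", "digest", "analyze", "run")) {
      .cli_usage()
      stop("unknown command: ", command)
    }
    overrides <- list()
    if (!is.null(opts$output_dir)) overrides$output_dir <- opts$output_dir
    if (!is.null(opts$seed)) overrides$seed <- opts$seed
    cfg <- read_run_config(opts$config, overrides)
    switch(command,
      prepare = cmd_prepare(cfg),
      digest = cmd_digest(cfg),
      analyze = cmd_analyze(cfg),
      run = run_pipeline(cfg))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
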