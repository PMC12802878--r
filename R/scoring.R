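# Protease score: weighted geometric mean of workflow/control ratios of
# identified proteins, identified peptides and mean sequence coverage.

#' Compute the protease score
#'
#' For a protein group and a workflow A compared against a control C,
#'
#' \deqn{S = \left[
#'   \left(\frac{N_{Prot,A}}{N_{Prot,C}}\right)^{W_{Prot}}
#'   \left(\frac{N_{Pep,A}}{N_{Pep,C}}\right)^{W_{Pep}}
#'   \left(\frac{COV_A}{COV_C}\right)^{W_{COV}}
#'   \right]^{1/(W_{Prot}+W_{Pep}+W_{COV})}}
#'
#' Scores above 1 mean the workflow outperforms the control in this
#' weighted geometric sense.  If any control quantity is 0 the score is
#' undefined: `NaN` is returned with a warning rather than an error.
#'
#' @param a,c Numeric vectors `c(n_prot, n_pep, mean_cov)` for the workflow
#'   and the control, or data frames with those three columns (vectorised
#'   row-wise).
#' @param weights Non-negative weights `c(W_Prot, W_Pep, W_COV)`; their sum
#'   must be positive.  Scaling all weights by a constant leaves the score
#'   unchanged.
#' @param label Optional label (group/combination) used in the warning for
#'   undefined scores.
#' @return Numeric score (vector if `a`/`c` are data frames).
#' @examples
#' protease_score(c(120, 900, 0.35), c(100, 1000, 0.30))
#' @export
protease_score <- function(a, c, weights = c(1, 1, 1), label = NULL) {
  if (is.data.frame(a)) a <- as.matrix(a) else a <- matrix(a, nrow = 1L)
  if (is.data.frame(c)) c <- as.matrix(c) else c <- matrix(c, nrow = 1L)
  stopifnot(ncol(a) == 3L, ncol(c) == 3L)
  if (nrow(c) == 1L && nrow(a) > 1L)
    c <- c[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(c))
  w <- as.numeric(weights)
  if (length(w) != 3L || any(w < 0) || sum(w) <= 0)
    stop("weights must be three non-negative values with positive sum")
  bad <- apply(c <= 0, 1L, any)
  lg <- log(a / c)
  lg[, w == 0] <- 0  # zero-weight components must not inject NaN/Inf
  s <- exp(as.vector(lg %*% w) / sum(w))  # exp(-Inf) = 0 when workflow is 0
  if (any(bad)) {
    warning("undefined protease score (control quantity is 0)",
            if (!is.null(label)) paste0(" for ", label) else "")
    s[bad] <- NaN
  }
  unname(s)
}

#' Enumerate protease combinations
#'
#' All non-empty subsets of the given proteases up to size `max_k`, ordered
#' by size and then lexicographically by the joined label.
#'
#' @param proteases Character vector of protease names.
#' @param max_k Maximal subset size (`1 <= max_k <= length(proteases)`).
#' @return List of character vectors (each in input order).
#' @examples
#' length(enumerate_combinations(letters[1:5], 5))  # 31
#' @export
enumerate_combinations <- function(proteases, max_k = length(proteases)) {
  stopifnot(max_k >= 1, max_k <= length(proteases))
  out <- list()
  for (k in seq_len(max_k)) {
    cmb <- combn(proteases, k, simplify = FALSE)
    lbl <- vapply(cmb, paste, character(1), collapse = "+")
    out <- c(out, cmb[order(lbl)])
  }
  out
}

#' Score every round against the control workflow
#'
#' Joins each per-round result row with the control combination's row from
#' the same virtual sample, group and inference rule (paired per-round
#' normalisation) and computes the protease score.
#'
#' @param rounds Per-round tibble from [run_monte_carlo()].
#' @param control Control combination: protease name(s); joined with `+` it
#'   must appear among the scored combinations (default `"trypsin"`).
#' @param weights Score weights `c(W_Prot, W_Pep, W_COV)`.
#' @return `rounds` with an added `score` column.
#' @export
score_rounds <- function(rounds, control = "trypsin",
                         weights = c(1, 1, 1)) {
  control_label <- paste(control, collapse = "+")
  ctrl <- rounds[rounds$combination == control_label, , drop = FALSE]
  if (nrow(ctrl) == 0L)
    stop("control combination '", control_label,
         "' not found among scored combinations")
  ctrl <- ctrl %>%
    select(sample_index, group, rule,
           c_prot = n_prot, c_pep = n_pep, c_cov = mean_cov)
  j <- left_join(rounds, ctrl, by = c("sample_index", "group", "rule"))
  j$score <- suppressWarnings(protease_score(
    j[, c("n_prot", "n_pep", "mean_cov")],
    setNames(j[, c("c_prot", "c_pep", "c_cov")],
             c("n_prot", "n_pep", "mean_cov")),
    weights))
  nan_rows <- which(is.nan(j$score))
  if (length(nan_rows))
    warning("undefined protease score for ",
            length(nan_rows), " round-level cell(s), e.g. ",
            paste(unique(paste0(j$combination[nan_rows], "/",
                                j$group[nan_rows], "/",
                                j$rule[nan_rows]))[1:min(3, length(nan_rows))],
                  collapse = ", "),
            " (control quantity is 0)")
  j[, c("sample_index", "combination", "group", "rule",
        "n_prot", "n_pep", "mean_cov", "score")]
}

#' Summarise scores across sampling rounds
#'
#' Mean and sample standard deviation of the score per
#' (combination, group, rule); undefined (`NaN`) rounds are excluded and
#' counted.  With a single retained round the SD is reported as 0.
#'
#' @param scored Tibble from [score_rounds()].
#' @return Tibble `combination`, `group`, `rule`, `score_mean`, `score_sd`,
#'   `n_rounds`, `n_nan`.
#' @export
summarize_scores <- function(scored) {
  scored %>%
    group_by(combination, group, rule) %>%
    summarise(
      n_nan = sum(is.nan(score)),
      n_rounds = sum(!is.nan(score)),
      score_mean = if (n_rounds[1] > 0) mean(score[!is.nan(score)])
                   else NaN,
      score_sd = if (n_rounds[1] > 1) sd(score[!is.nan(score)]) else 0,
      .groups = "drop"
    ) %>%
    select(combination, group, rule, score_mean, score_sd,
           n_rounds, n_nan) %>%
    arrange(nchar(gsub("[^+]", "", combination)), combination, group, rule)
}

#' Write per-round and summary score tables
#'
#' Serialises the scored rounds to `results.tsv` and the summary to
#' `results_summary.tsv` in `dir`.
#'
#' @param scored Tibble from [score_rounds()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_score_tables <- function(scored, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res_path <- file.path(dir, "results.tsv")
  sum_path <- file.path(dir, "results_summary.tsv")
  readr::write_tsv(scored, res_path, progress = FALSE)
  readr::write_tsv(summarize_scores(scored), sum_path, progress = FALSE)
  invisible(c(results = res_path, summary = sum_path))
}
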