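# Run configuration: a flat YAML key-value file validated before any
# computation.

#' Default run configuration
#'
#' Returns the configuration defaults as a named list; [read_run_config()]
#' merges a YAML file over these.  Keys: `fasta`, `output_dir`, `seed`,
#' `n_samples`, `groups`, `abundance` (`location`, `scale`,
#' `undetectable_fraction`), `proteases`, `mc_fractions` (per-protease
#' overrides), `peptides_per_protease`, `max_mc`, `filter`,
#' `require_unique`, `detectability` (`source`: `uniform` / `heuristic` /
#' `file`, plus `path`), `control`, `weights`, `max_k`,
#' `with_replacement`.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    fasta = NULL,
    output_dir = "proteasim_run",
    seed = 1L,
    n_samples = 10L,
    groups = list(
      list(label = "small", min_length = 1, max_length = 70),
      list(label = "large", min_length = 71, max_length = Inf)
    ),
    abundance = list(distribution = "lognormal", location = 0, scale = 2,
                     undetectable_fraction = 0.45),
    proteases = c("trypsin", "lys_c", "chymotrypsin", "glu_c",
                  "lysarginase"),
    mc_fractions = list(),
    peptides_per_protease = 10000L,
    max_mc = NULL,
    filter = list(min_length = 6, max_length = 45,
                  min_mass = 400, max_mass = 6000),
    require_unique = TRUE,
    detectability = list(source = "uniform", path = NULL),
    control = "trypsin",
    weights = c(1, 1, 1),
    max_k = NULL,
    with_replacement = FALSE
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration, merges it over [default_run_config()],
#' resolves proteases / groups / filter / detectability into their package
#' objects and validates everything before any computation.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @param overrides Named list applied on top of the file (e.g. a `--seed`
#'   command-line override).
#' @return Validated configuration of class `run_config`, with resolved
#'   components in `$resolved`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("configuration file is not a YAML mapping")
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  if (length(overrides)) cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Raw configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$fasta))
    stop("configuration must name a 'fasta' protein database")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_samples <- as.integer(cfg$n_samples)
  if (cfg$n_samples < 1L) stop("n_samples must be >= 1")
  groups <- bind_rows(lapply(cfg$groups, function(g) {
    mx <- g$max_length
    if (is.character(mx) || is.null(mx)) mx <- Inf
    tibble(label = g$label, min_length = as.numeric(g$min_length),
           max_length = as.numeric(mx))
  }))
  validate_groups(groups)
  uf <- cfg$abundance$undetectable_fraction
  if (is.list(uf)) uf <- unlist(uf)
  model <- abundance_model(
    distribution = cfg$abundance$distribution %||% "lognormal",
    location = cfg$abundance$location %||% 0,
    scale = cfg$abundance$scale %||% 2,
    undetectable_fraction = uf %||% 0.45)
  specs <- resolve_proteases(cfg$proteases)
  for (nm in names(cfg$mc_fractions)) {
    if (!nm %in% names(specs))
      stop("mc_fractions override for protease not in run: ", nm)
    specs[[nm]] <- with_mc_fractions(specs[[nm]],
                                     as.numeric(cfg$mc_fractions[[nm]]))
  }
  flt <- peptide_filter(
    min_length = cfg$filter$min_length %||% 6,
    max_length = cfg$filter$max_length %||% 45,
    min_mass = cfg$filter$min_mass %||% 400,
    max_mass = cfg$filter$max_mass %||% 6000)
  det <- switch(
    cfg$detectability$source %||% "uniform",
    uniform = uniform_detectability(),
    heuristic = heuristic_detectability(),
    file = {
      if (is.null(cfg$detectability$path))
        stop("detectability source 'file' requires a 'path'")
      load_detectability(cfg$detectability$path)
    },
    stop("unknown detectability source: ", cfg$detectability$source))
  control <- unlist(cfg$control)
  missing_ctrl <- setdiff(control, names(specs))
  if (length(missing_ctrl))
    stop("control protease(s) not part of the run: ",
         paste(missing_ctrl, collapse = ", "))
  if (is.null(cfg$max_k)) cfg$max_k <- min(7L, length(specs))
  cfg$max_k <- as.integer(cfg$max_k)
  if (cfg$max_k < 1L || cfg$max_k > length(specs))
    stop("max_k must be between 1 and the number of proteases")
  ppp <- cfg$peptides_per_protease
  if (is.list(ppp)) ppp <- unlist(ppp)
  weights <- as.numeric(unlist(cfg$weights))
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be three non-negative values with positive sum")
  cfg$resolved <- list(groups = groups, model = model, proteases = specs,
                       filter = flt, detectability = det,
                       control = control,
                       peptides_per_protease = ppp, weights = weights)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
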