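# Protease cleavage rules and missed-cleavage frequency models.

#' Define a protease
#'
#' A protease is described by the residues it recognises, whether it cleaves
#' C- or N-terminally of the matched residue, an optional set of residues
#' that block cleavage when they immediately follow the cut site (classically
#' proline for trypsin), and a missed-cleavage (MC) frequency distribution:
#' `mc_fractions[m + 1]` is the expected fraction of identified peptides
#' carrying exactly `m` missed cleavages.
#'
#' @param name Protease name (used in outputs and combination labels).
#' @param residues Character vector of single-letter residues at the cut site.
#' @param side `"C"` (cut after the matched residue) or `"N"` (cut before it).
#' @param blocked_next Residues that suppress cleavage when they directly
#'   follow the cut position (only meaningful for C-terminal cutters).
#' @param mc_fractions Numeric vector over MC counts `0..max_mc`; must sum
#'   to 1 (within 1e-9).  Its length fixes the maximal MC count considered.
#' @return An object of class `protease_spec`.
#' @examples
#' protease_spec("lys_c", "K", "C", mc_fractions = c(0.8, 0.15, 0.04, 0.01))
#' @export
protease_spec <- function(name, residues, side = c("C", "N"),
                          blocked_next = character(),
                          mc_fractions = 1) {
  side <- match.arg(side)
  residues <- toupper(unlist(strsplit(residues, "", fixed = TRUE)))
  blocked_next <- toupper(unlist(strsplit(blocked_next, "", fixed = TRUE)))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(residues) == 0L)
    stop("protease_spec(): 'residues' must be non-empty")
  mc_fractions <- as.numeric(mc_fractions)
  if (length(mc_fractions) < 1L || any(mc_fractions < 0))
    stop("protease_spec(): mc_fractions must be non-negative")
  if (abs(sum(mc_fractions) - 1) > 1e-9)
    stop("protease_spec(): mc_fractions must sum to 1 (got ",
         format(sum(mc_fractions)), ")")
  structure(
    list(name = name, residues = residues, side = side,
         blocked_next = blocked_next, mc_fractions = mc_fractions,
         max_mc = length(mc_fractions) - 1L),
    class = "protease_spec"
  )
}

#' @export
print.protease_spec <- function(x, ...) {
  cat("<protease_spec> ", x$name, ": cleaves ",
      if (x$side == "C") "C-terminal" else "N-terminal",
      " of [", paste(x$residues, collapse = ""), "]",
      if (length(x$blocked_next))
        paste0(", blocked before [", paste(x$blocked_next, collapse = ""), "]")
      else "",
      "; max MC ", x$max_mc, "\n", sep = "")
  invisible(x)
}

# Default MC frequency vectors (fractions of peptides with 0..5 MCs).
# These are configurable stand-in distributions, qualitatively consistent
# with published multi-protease digestion surveys: Arg-C digestion is almost
# complete, chymotrypsin leaves only ~20% of peptides fully cleaved, trypsin
# and LysArgiNase sit in between with most mass at 0-1 MC.
.default_mc <- list(
  trypsin      = c(0.60, 0.25, 0.10, 0.03, 0.015, 0.005),
  lys_c        = c(0.80, 0.15, 0.04, 0.01, 0, 0),
  arg_c        = c(0.95, 0.04, 0.01, 0, 0, 0),
  chymotrypsin = c(0.20, 0.35, 0.25, 0.12, 0.05, 0.03),
  glu_c        = c(0.55, 0.25, 0.12, 0.05, 0.02, 0.01),
  lysarginase  = c(0.60, 0.25, 0.10, 0.03, 0.015, 0.005),
  lys_n        = c(0.70, 0.20, 0.07, 0.02, 0.01, 0),
  asp_n        = c(0.55, 0.25, 0.12, 0.05, 0.02, 0.01)
)

#' Built-in protease catalogue
#'
#' Returns the catalogue of pre-defined proteases.  Each entry is a
#' [protease_spec()] and is fully overridable: pass modified specs (or
#' different `mc_fractions`) to the digestion and simulation functions.
#'
#' Entries: `trypsin` (K/R, C-terminal, proline block) and `trypsin_p`
#' (no proline block); `lys_c` (K, C-terminal); `arg_c` (R, C-terminal);
#' `chymotrypsin` (F/W/Y/L, C-terminal, proline block) and
#' `chymotrypsin_fwy` (strict F/W/Y); `glu_c` (E, C-terminal) and
#' `glu_c_de` (E/D); `lysarginase` (K/R, N-terminal); `lys_n`
#' (K, N-terminal); `asp_n` (D, N-terminal).
#'
#' @return Named list of `protease_spec` objects.
#' @export
protease_catalogue <- function() {
  list(
    trypsin = protease_spec("trypsin", c("K", "R"), "C", "P",
                            .default_mc$trypsin),
    trypsin_p = protease_spec("trypsin_p", c("K", "R"), "C",
                              mc_fractions = .default_mc$trypsin),
    lys_c = protease_spec("lys_c", "K", "C", mc_fractions = .default_mc$lys_c),
    arg_c = protease_spec("arg_c", "R", "C", mc_fractions = .default_mc$arg_c),
    chymotrypsin = protease_spec("chymotrypsin", c("F", "W", "Y", "L"), "C",
                                 "P", .default_mc$chymotrypsin),
    chymotrypsin_fwy = protease_spec("chymotrypsin_fwy", c("F", "W", "Y"),
                                     "C", "P", .default_mc$chymotrypsin),
    glu_c = protease_spec("glu_c", "E", "C", mc_fractions = .default_mc$glu_c),
    glu_c_de = protease_spec("glu_c_de", c("E", "D"), "C",
                             mc_fractions = .default_mc$glu_c),
    lysarginase = protease_spec("lysarginase", c("K", "R"), "N",
                                mc_fractions = .default_mc$lysarginase),
    lys_n = protease_spec("lys_n", "K", "N",
                          mc_fractions = .default_mc$lys_n),
    asp_n = protease_spec("asp_n", "D", "N", mc_fractions = .default_mc$asp_n)
  )
}

#' Resolve protease names or specs against the catalogue
#'
#' @param proteases Character vector of catalogue names, a single
#'   `protease_spec`, or a list mixing names and `protease_spec` objects.
#' @return Named list of `protease_spec` objects, in input order.
#' @export
resolve_proteases <- function(proteases) {
  cat_ <- protease_catalogue()
  if (inherits(proteases, "protease_spec")) proteases <- list(proteases)
  if (is.character(proteases)) proteases <- as.list(proteases)
  specs <- lapply(proteases, function(p) {
    if (inherits(p, "protease_spec")) return(p)
    if (is.character(p) && length(p) == 1L) {
      if (!p %in% names(cat_))
        stop("unknown protease '", p, "'; catalogue: ",
             paste(names(cat_), collapse = ", "))
      return(cat_[[p]])
    }
    stop("proteases must be catalogue names or protease_spec objects")
  })
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate protease names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(specs) <- nm
  specs
}

#' Replace the missed-cleavage distribution of a protease
#'
#' @param spec A `protease_spec`.
#' @param mc_fractions New MC frequency vector (sums to 1).
#' @return The modified `protease_spec`.
#' @export
with_mc_fractions <- function(spec, mc_fractions) {
  protease_spec(spec$name, spec$residues, spec$side, spec$blocked_next,
                mc_fractions)
}
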