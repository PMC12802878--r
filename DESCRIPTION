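Package: proteasim
Title: Monte-Carlo Prediction of Protease Scores for Multi-Protease
    Bottom-Up Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts, before any mass-spectrometry measurement, how well a
    combination of proteolytic enzymes will characterise a proteome or a
    subset of it (for example small proteins of at most 70 amino acids).
    Proteins from a FASTA database are grouped by length and assigned
    simulated abundances; each protease digests the proteome in silico with
    an explicit missed-cleavage model; peptide identification is simulated
    by weighted random sampling; and identified proteins are inferred from
    the sampled peptides.  Every protease combination is then summarised by
    a protease score, the weighted geometric mean of the ratios of
    identified-protein count, identified-peptide count and mean sequence
    coverage relative to a control digest (trypsin by default).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
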