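# Example proteasim run configuration.
# Any key left out falls back to the package default (see
# ?default_run_config).

fasta: proteome.fasta
output_dir: proteasim_run
seed: 1
n_samples: 10

groups:
  - {label: small, min_length: 1, max_length: 70}
  - {label: large, min_length: 71, max_length: .inf}

abundance:
  distribution: lognormal
  location: 0
  scale: 2
  undetectable_fraction: 0.45    # may also be a map: {small: 0.45, large: 0.2}

proteases: [trypsin, lys_c, chymotrypsin, glu_c, lysarginase]

# optional per-protease missed-cleavage frequency overrides
# (fractions over 0..max MC, must sum to 1); [1] means complete digestion
mc_fractions:
  # trypsin: [0.7, 0.2, 0.07, 0.02, 0.01, 0]

peptides_per_protease: 10000     # scalar or map {trypsin: 12000, ...}

filter:
  min_length: 6
  max_length: 45
  min_mass: 400
  max_mass: 6000

require_unique: true             # false switches to protein-group mode

detectability:
  source: uniform                # uniform | heuristic | file
  path: null                     # TSV with columns: peptide, score

control: trypsin                 # protease name or list of names
weights: [1, 1, 1]               # W_Prot, W_Pep, W_COV
max_k: 5                         # largest combination size
with_replacement: false
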