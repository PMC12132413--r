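# Example pipeline configuration: all module defaults, stated explicitly.
# Seeds are mandatory; every other field falls back to these values when
# omitted.
seed: 1
design:
  mutation_rate: 0.1        # substitutions per position
  n_variants: 1500          # mutants per promoter (wild type added on top)
  barcode_length: 20        # bases
  median_barcodes: 13       # realized median barcodes per variant
simulate:
  conditions: [condA, condB]
  active_in: condA          # conditions where the planted activator is on
  with_repressor: true
  depth_dna: 1.0e6          # reads per DNA sample
  depth_rna: 1.0e6          # reads per RNA sample
  replicates: 2
footprint:
  pseudocount: 0.5          # per cell of each 2x2 table
discover:
  kernel_sigma: 3           # bases
  cv_ratio_threshold: 0.5   # CV_smooth / CV_raw boundary (spike vs sites)
  activity_threshold: 0.6   # minimum smoothed CV for an active footprint
  posterior_cut: 0.5        # HMM site-state probability
  merge_gap: 2              # bridge gaps up to this many bases
  min_length: 4             # drop shorter calls
cluster:
  replicate_floor: 0.3      # Pearson r below which a replicate pair is flagged
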