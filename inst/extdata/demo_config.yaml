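# Planted-cluster demonstration: a 20x20 block-group grid with an
# under-treatment region (odds ratio 1.5) around the grid center and a
# 20,000-case cohort at the default case-mix prevalences. Running the
# pipeline on this config recovers a significant low-RAAP cluster
# overlapping the planted region.
synth:
  grid_rows: 20
  grid_cols: 20
  n_patients: 20000
  planted_undertreat_or: 1.5
scan:
  max_fraction: 0.5
  reps: 999
  alpha: 0.05
seed: 42
moran_permutations: 999
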