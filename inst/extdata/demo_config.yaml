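# Small synthetic demo run: 26 samples, 40-miRNA panel, reduced grids.
# All data are simulated; seeds may be overridden with --seed.
seed: 5
out_dir: mirpanel_demo_out
synthetic:
  n_per_class: [8, 10, 8]
  n_mirnas: 40
  n_low_detection: 6
  n_spike_ins: 3
  seed: 1
cv:
  outer_folds: 3
  inner_folds: 2
lr_grid:
  feature_percentages: [20]
  inv_regularization: [0.1, 10]
  l1_ratios: [0, 1]
rf_grid:
  max_depths: [3]
  bootstrap: [true]
  max_features: [sqrt]
  criterion: [gini]
  n_trees: 50
enrichment:
  n_permutations: 99
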