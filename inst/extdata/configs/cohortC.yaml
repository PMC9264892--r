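# Imbalanced design: 100 cases vs 35 symptomatic controls, SMOTE
# rebalancing of the training split, moderate class effect.
cohort:
  n_cases: 100
  n_controls: 35
  effect_size: 1.5
  seed: 103
prep:
  emsc_order: 2
  crop_high: 1800
  crop_low: 1000
  normalization: vector
  bin_factor: 8
models: [plsda, rf, svm_linear]
n_repeats: 51
sampling: smote
perm_iters: 1000
perm_family: plsda
base_seed: 3
outdir: results/cohortC
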