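# Balanced discovery design: 100 cases vs 100 healthy controls,
# strong spectral effect, no rebalancing.
cohort:
  n_cases: 100
  n_controls: 100
  effect_size: 3
  seed: 101
prep:
  emsc_order: 2
  crop_high: 1800
  crop_low: 1000
  normalization: vector
  bin_factor: 8
models: [plsda, rf, svm_linear]
n_repeats: 51
sampling: none
perm_iters: 1000
perm_family: plsda
base_seed: 1
outdir: results/cohortA
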