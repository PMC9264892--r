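# Balanced symptomatic-control design: 35 cases vs 35 symptomatic controls.
# Symptomatic controls share confounding features with cases, so the class
# effect is moderate rather than strong.
cohort:
  n_cases: 35
  n_controls: 35
  effect_size: 1.5
  seed: 102
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
base_seed: 2
outdir: results/cohortB
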