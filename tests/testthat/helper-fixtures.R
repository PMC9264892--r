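# Shared fixtures: small synthetic cohorts and hand-built datasets.

# fingerprint-only axis keeps unit tests fast; preprocessing still crops it
fp_axis <- function(spacing = 2) make_axis(1900, 900, spacing)

tiny_cohort <- function(n_cases = 6, n_controls = 6, effect_size = 3,
                        seed = 1, axis = fp_axis(), ...) {
  simulate_cohort(cohort_config(n_cases = n_cases, n_controls = n_controls,
                                effect_size = effect_size, seed = seed, ...),
                  axis = axis)
}

# dataset built by hand: known matrix, n patients x 9 replicates
handmade_dataset <- function(n_patients = 2, n_points = 5,
                             axis = seq(1800, by = -2,
                                        length.out = n_points)) {
  n <- n_patients * 9L
  meta <- data.frame(
    patient_id = rep(sprintf("p%02d", seq_len(n_patients)), each = 9L),
    class = rep(rep(c("cancer", "control"), length.out = n_patients),
                each = 9L),
    bio_rep = rep(rep(1:3, each = 3L), n_patients),
    tech_rep = rep(1:3, 3L * n_patients))
  set.seed(42)
  spectral_dataset(matrix(rnorm(n * n_points), n), axis, meta)
}

write_jcamp_fixture <- function(path, lines) {
  writeLines(lines, path)
  path
}
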