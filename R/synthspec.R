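#' Build a wavenumber axis
#'
#' Strictly decreasing grid from `high` to `low` cm^-1. The default mirrors
#' a mid-infrared acquisition over 4000-450 cm^-1 digitized at 2 cm^-1
#' (half the 4 cm^-1 instrument resolution), giving 1776 points.
#'
#' @param high,low axis end points, cm^-1 (`high > low`).
#' @param spacing grid spacing, cm^-1 (> 0).
#' @return numeric vector of wavenumbers, high to low.
#' @export
make_axis <- function(high = 4000, low = 450, spacing = 2) {
  if (!(high > low)) stop("make_axis: high must exceed low", call. = FALSE)
  if (!(spacing > 0)) stop("make_axis: spacing must be > 0", call. = FALSE)
  span <- high - low
  if (abs(span / spacing - round(span / spacing)) > 1e-9)
    warning("axis span not divisible by spacing; grid ends at ",
            high - spacing * floor(span / spacing), " cm-1")
  seq(high, by = -spacing, length.out = floor(span / spacing) + 1L)
}

#' Describe a Gaussian absorption band
#'
#' @param center band center, cm^-1.
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param amplitude peak absorbance (>= 0).
#' @return a one-row data.frame with columns `center`, `width`, `amplitude`.
#' @export
band_spec <- function(center, width, amplitude) {
  stopifnot(width > 0, amplitude >= 0)
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Default serum absorption band library
#'
#' Major mid-infrared serum features: amide A (N-H stretch, ~3300), C-H
#' stretch (~2960), amide I (C=O stretch, ~1650), amide II (N-H bend / C-N
#' stretch, ~1545), asymmetric phosphate stretch (~1240), carbohydrate
#' C-O-C stretches (~1100, ~1040). Amplitudes are plausible dried-film
#' absorbances, not claimed serum values.
#'
#' @return data.frame of [band_spec()] rows.
#' @export
serum_bands <- function() {
  rbind(
    band_spec(3300, 120, 0.35),
    band_spec(2960, 25, 0.15),
    band_spec(1650, 25, 1.00),
    band_spec(1545, 22, 0.65),
    band_spec(1450, 18, 0.20),
    band_spec(1400, 15, 0.15),
    band_spec(1240, 25, 0.15),
    band_spec(1100, 20, 0.12),
    band_spec(1040, 18, 0.12)
  )
}

#' Default class-difference bands
#'
#' Where the case-control contrast is planted: the amide II flanks (~1570
#' and ~1500 cm^-1) plus phosphate (~1270) and carbohydrate (~1050) bands,
#' the regions implicated by importance profiling in serum cancer studies.
#'
#' @return data.frame of [band_spec()] rows with unit-scale amplitudes;
#'   [cohort_config()]'s `effect_size` multiplies them.
#' @export
effect_bands_default <- function() {
  rbind(
    band_spec(1570, 10, 0.020),
    band_spec(1500, 10, 0.020),
    band_spec(1270, 12, 0.010),
    band_spec(1050, 12, 0.010)
  )
}

#' Evaluate a sum of Gaussian bands on an axis
#'
#' @param axis wavenumber grid, cm^-1.
#' @param bands data.frame of [band_spec()] rows.
#' @return non-negative intensity vector, one value per axis point.
#' @export
base_serum_spectrum <- function(axis, bands = serum_bands()) {
  if (is.null(bands) || nrow(bands) == 0L)
    stop("base_serum_spectrum: band list must be non-empty", call. = FALSE)
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    y <- y + bands$amplitude[i] *
      exp(-(axis - bands$center[i])^2 / (2 * bands$width[i]^2))
  }
  y
}

#' Configure a synthetic cohort
#'
#' Defaults encode the replicate design of a serum ATR-FTIR study — three
#' biological replicates (separately deposited films) each measured three
#' times, nine spectra per patient — plus noise scales chosen so that
#' between-patient variation dominates between-film variation, which in
#' turn dominates instrument noise.
#'
#' @param n_cases,n_controls patient counts per class.
#' @param n_bio,n_tech biological / technical replicates per patient.
#' @param effect_size dimensionless multiplier on `effect_bands` amplitudes
#'   added to case spectra (0 = null cohort).
#' @param effect_bands data.frame of [band_spec()] rows carrying the class
#'   difference.
#' @param patient_sd,bio_sd relative SD of per-patient / per-film band
#'   amplitude jitter (fraction of each band's amplitude).
#' @param effect_jitter_sd absolute SD (absorbance) of per-patient
#'   amplitude jitter on the `effect_bands` themselves, applied to both
#'   classes; biological replicates add a further third of it. This is the
#'   disease-independent variation of the discriminatory bands, so
#'   `effect_size` is expressed in units of between-patient variability:
#'   the per-band standardized class separation is approximately
#'   `effect_size * 0.02 / effect_jitter_sd`.
#' @param tech_sd SD of i.i.d. per-point instrument noise (absorbance).
#' @param scatter_sd log-scale SD of the multiplicative scatter factor.
#' @param baseline_order polynomial degree of the additive baseline drift.
#' @param baseline_sd SD of the random baseline coefficients (absorbance).
#' @param bands base serum band library (data.frame of [band_spec()] rows).
#' @param seed integer RNG seed; fixed seed implies a bit-identical cohort.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 100, n_controls = 100,
                          n_bio = 3, n_tech = 3,
                          effect_size = 1,
                          effect_bands = effect_bands_default(),
                          patient_sd = 0.06, bio_sd = 0.02,
                          tech_sd = 0.002,
                          effect_jitter_sd = 0.02,
                          scatter_sd = 0.1,
                          baseline_order = 2, baseline_sd = 0.02,
                          bands = serum_bands(),
                          seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
              effect_size = effect_size, effect_bands = effect_bands,
              patient_sd = patient_sd, bio_sd = bio_sd, tech_sd = tech_sd,
              effect_jitter_sd = effect_jitter_sd,
              scatter_sd = scatter_sd, baseline_order = as.integer(baseline_order),
              baseline_sd = baseline_sd, bands = bands,
              seed = as.integer(seed))
  stopifnot(cfg$n_cases >= 1L, cfg$n_controls >= 1L,
            cfg$n_bio >= 1L, cfg$n_tech >= 1L,
            cfg$patient_sd >= 0, cfg$bio_sd >= 0, cfg$tech_sd >= 0,
            cfg$effect_jitter_sd >= 0,
            cfg$scatter_sd >= 0, cfg$baseline_sd >= 0,
            cfg$baseline_order >= 0)
  structure(cfg, class = "cohort_config")
}

#' Simulate a serum-like spectral cohort
#'
#' Generative model per spectrum:
#' \deqn{y = b (base + z \cdot effect + patient + film) + baseline + noise}
#' where `z` is 1 for cases and 0 for controls, `b = exp(N(0, scatter_sd))`
#' is a multiplicative scatter factor, `patient` and `film` deviations are
#' smooth band-amplitude jitters drawn once per patient and per biological
#' replicate (covering the base bands and, crucially, the effect bands, so
#' the discriminatory directions carry disease-independent biological
#' variation), `baseline` is a random polynomial of the configured degree and
#' `noise` is i.i.d. Gaussian per point. Multiplicative scatter is applied
#' before the additive baseline, so an EMSC model (reference scale +
#' polynomial) is its exact inverse.
#'
#' Each patient consumes an RNG stream seeded deterministically from
#' `cfg$seed` and the patient counter, so any patient subset is
#' reproducible in isolation.
#'
#' @param cfg a [cohort_config()].
#' @param axis wavenumber grid (default [make_axis()]).
#' @return a [spectral_dataset()] with `n_bio * n_tech` spectra per patient.
#' @export
simulate_cohort <- function(cfg, axis = make_axis()) {
  stopifnot(inherits(cfg, "cohort_config"))
  base <- base_serum_spectrum(axis, cfg$bands)
  effect <- if (cfg$effect_size > 0 && nrow(cfg$effect_bands) > 0) {
    cfg$effect_size * base_serum_spectrum(axis, cfg$effect_bands)
  } else numeric(length(axis))
  shapes <- band_shape_matrix(axis, cfg$bands)   # n_points x n_bands
  amps <- cfg$bands$amplitude
  eff_shapes <- if (nrow(cfg$effect_bands) > 0)
    band_shape_matrix(axis, cfg$effect_bands) else NULL
  n_eff <- if (is.null(eff_shapes)) 0L else ncol(eff_shapes)
  x01 <- scale_axis(axis)                        # rescaled to [-1, 1]
  n_pat <- cfg$n_cases + cfg$n_controls
  per_pat <- cfg$n_bio * cfg$n_tech
  mat <- matrix(0, nrow = n_pat * per_pat, ncol = length(axis))
  meta <- data.frame(
    patient_id = character(n_pat * per_pat), class = character(n_pat * per_pat),
    bio_rep = integer(n_pat * per_pat), tech_rep = integer(n_pat * per_pat),
    stringsAsFactors = FALSE)
  row <- 0L
  for (p in seq_len(n_pat)) {
    is_case <- p <= cfg$n_cases
    pid <- if (is_case) sprintf("case_%03d", p)
           else sprintf("ctrl_%03d", p - cfg$n_cases)
    set.seed(patient_seed(cfg$seed, p))
    patient_dev <- drop(shapes %*% stats::rnorm(length(amps),
                                                sd = cfg$patient_sd * amps))
    if (n_eff > 0L)
      patient_dev <- patient_dev +
        drop(eff_shapes %*% stats::rnorm(n_eff, sd = cfg$effect_jitter_sd))
    signal_pat <- base + if (is_case) effect else 0
    for (b in seq_len(cfg$n_bio)) {
      bio_dev <- drop(shapes %*% stats::rnorm(length(amps),
                                              sd = cfg$bio_sd * amps))
      if (n_eff > 0L)
        bio_dev <- bio_dev +
          drop(eff_shapes %*% stats::rnorm(n_eff,
                                           sd = cfg$effect_jitter_sd / 3))
      film <- signal_pat + patient_dev + bio_dev
      for (t in seq_len(cfg$n_tech)) {
        bfac <- exp(stats::rnorm(1L, sd = cfg$scatter_sd))
        coefs <- stats::rnorm(cfg$baseline_order + 1L, sd = cfg$baseline_sd)
        baseline <- drop(outer(x01, 0:cfg$baseline_order, `^`) %*% coefs)
        noise <- stats::rnorm(length(axis), sd = cfg$tech_sd)
        row <- row + 1L
        mat[row, ] <- bfac * film + baseline + noise
        meta$patient_id[row] <- pid
        meta$class[row] <- if (is_case) "cancer" else "control"
        meta$bio_rep[row] <- b
        meta$tech_rep[row] <- t
      }
    }
  }
  spectral_dataset(mat, axis, meta)
}

# per-patient RNG substream seed, kept inside 32-bit integer range
patient_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 16807) %% 2147483647)
}

band_shape_matrix <- function(axis, bands) {
  vapply(seq_len(nrow(bands)), function(i) {
    exp(-(axis - bands$center[i])^2 / (2 * bands$width[i]^2))
  }, numeric(length(axis)))
}

scale_axis <- function(axis) {
  2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
}
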