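# independent least-squares oracle for EMSC: generic lm fit per spectrum
emsc_oracle <- function(x, ref, axis, order) {
  P <- serodisc:::legendre_design(serodisc:::scale_axis(axis), order)
  cf <- stats::coef(stats::lm(x ~ 0 + cbind(ref, P)))
  list(corrected = (x - drop(P %*% cf[-1L])) / cf[1L],
       b = unname(cf[1L]), c = unname(cf[-1L]))
}

test_that("EMSC recovers exact linear models of the reference", {
  ds <- handmade_dataset(n_patients = 1, n_points = 60)
  ref <- base_serum_spectrum(ds$axis, band_spec(1750, 20, 1)) + 0.1
  m <- rbind(ref, 2 * ref + 5)
  ds2 <- spectral_dataset(m, ds$axis, ds$meta[1:2, ])
  out <- emsc_correct(ds2, ref, order = 2)
  fit <- attr(out, "emsc_fit")
  expect_equal(out$matrix[1, ], ref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(fit[1, ]), c(1, 0, 0, 0), tolerance = 1e-8)
  expect_equal(out$matrix[2, ], ref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(fit[2, c("b", "c0")]), c(2, 5), tolerance = 1e-8)
})

test_that("EMSC matches the normal-equations oracle on random spectra", {
  set.seed(101)
  for (order in 0:4) {
    n_pts <- sample(20:100, 1)
    axis <- seq(1800, by = -2, length.out = n_pts)
    ref <- base_serum_spectrum(axis, band_spec(1700, 30, 1)) + 0.2
    m <- matrix(rnorm(6 * n_pts, mean = 1), 6)
    meta <- data.frame(patient_id = as.character(1:6),
                       class = rep(c("cancer", "control"), 3),
                       bio_rep = 1L, tech_rep = 1:6)
    ds <- spectral_dataset(m, axis, meta)
    out <- emsc_correct(ds, ref, order)
    for (i in 1:6) {
      ora <- emsc_oracle(m[i, ], ref, axis, order)
      expect_lt(max(abs(out$matrix[i, ] - ora$corrected)), 1e-8)
      expect_lt(abs(attr(out, "emsc_fit")[i, "b"] - ora$b), 1e-8)
    }
  }
})

test_that("EMSC rejects degenerate and collinear inputs", {
  ds <- handmade_dataset(n_patients = 1, n_points = 30)
  expect_error(emsc_correct(ds, rep(0, 30), 2), "identically zero")
  # a constant reference is collinear with the polynomial offset
  expect_error(emsc_correct(ds, rep(1, 30), 2), "collinear")
  # a spectrum lying entirely in the polynomial space gives b ~ 0
  axis <- seq(1800, by = -2, length.out = 30)
  t1 <- serodisc:::legendre_design(serodisc:::scale_axis(axis), 1)[, 2]
  ref <- base_serum_spectrum(axis, band_spec(1750, 10, 1))
  meta <- data.frame(patient_id = c("a", "b"), class = c("cancer", "control"),
                     bio_rep = 1L, tech_rep = 1L)
  dsl <- spectral_dataset(rbind(t1, 2 * t1 + 1), axis, meta)
  expect_error(emsc_correct(dsl, ref, 1), "degenerate")
})

test_that("fingerprint cropping keeps the inclusive window", {
  ds <- tiny_cohort(n_cases = 1, n_controls = 1, axis = make_axis())
  out <- crop_region(ds, 1800, 1000)
  expect_equal(n_points(out), 401L)
  expect_equal(range(out$axis), c(1000, 1800))
  ident <- crop_region(ds, max(ds$axis), min(ds$axis))
  expect_equal(ident$matrix, ds$matrix)
  expect_error(crop_region(ds, 100, 50), "does not overlap")
})

test_that("vector normalization centres, scales and is affine-invariant", {
  ds <- handmade_dataset(n_patients = 2, n_points = 40)
  out <- vector_normalize(ds)
  expect_lt(max(abs(rowMeans(out$matrix))), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(out$matrix^2)) - 1)), 1e-12)
  shifted <- spectral_dataset(3.7 * ds$matrix + 11, ds$axis, ds$meta)
  expect_equal(vector_normalize(shifted)$matrix, out$matrix,
               tolerance = 1e-12)
  two <- spectral_dataset(matrix(c(1, -1), 1), c(1800, 1798),
                          ds$meta[1, ], validate = FALSE)
  expect_equal(drop(vector_normalize(two)$matrix),
               c(sqrt(2) / 2, -sqrt(2) / 2))
  flat <- spectral_dataset(matrix(5, 1, 4), seq(1800, 1794, -2),
                           ds$meta[1, ], validate = FALSE)
  expect_error(vector_normalize(flat), "zero-variance")
})

test_that("binning averages fixed-size groups and drops the remainder", {
  ds <- tiny_cohort(n_cases = 1, n_controls = 1,
                    axis = make_axis(1800, 1000, 2))
  expect_warning(out <- bin_spectra(ds, 8), "remainder of 1")
  expect_equal(n_points(out), 50L)
  expect_equal(out$matrix[, 1], rowMeans(ds$matrix[, 1:8]))
  expect_equal(out$axis[1], mean(ds$axis[1:8]))
  expect_identical(bin_spectra(ds, 1), ds)
  const <- spectral_dataset(matrix(2.5, 2, 16), seq(1830, 1800, -2),
                            ds$meta[1:2, ], validate = FALSE)
  binned <- bin_spectra(const, 8)
  expect_true(all(binned$matrix == 2.5))
  expect_error(bin_spectra(const, 17), "exceeds")
})

test_that("the default chain yields 50 features from the full axis", {
  ds <- tiny_cohort(n_cases = 2, n_controls = 2, axis = make_axis())
  out <- serodisc:::quiet_bin(run_preprocess(ds, preprocess_config()))
  expect_equal(n_points(out), 50L)
  expect_equal(n_spectra(out), 36L)
})

test_that("an identity-configured chain reduces to the crop", {
  axis <- make_axis(2000, 900, 2)
  ref <- base_serum_spectrum(axis) + 0.05
  meta <- data.frame(patient_id = c("a", "b"), class = c("cancer", "control"),
                     bio_rep = 1L, tech_rep = 1L)
  ds <- spectral_dataset(rbind(ref, ref), axis, meta)
  cfg <- preprocess_config(emsc_order = 0, normalization = "none",
                           bin_factor = 1, emsc_reference = "supplied")
  out <- run_preprocess(ds, cfg, reference = ref)
  expect_equal(out$matrix[1, ], crop_region(ds, 1800, 1000)$matrix[1, ],
               tolerance = 1e-10)
})

test_that("row order permutes through the chain unchanged", {
  ds <- tiny_cohort(n_cases = 2, n_controls = 2)
  perm <- sample(n_spectra(ds))
  ref <- colMeans(ds$matrix)
  cfg <- preprocess_config(emsc_reference = "supplied")
  a <- serodisc:::quiet_bin(run_preprocess(ds, cfg, reference = ref))
  b <- serodisc:::quiet_bin(run_preprocess(subset_rows(ds, perm), cfg,
                                           reference = ref))
  expect_equal(b$matrix, a$matrix[perm, ])
})

test_that("stage order is crop after EMSC, not before", {
  ds <- tiny_cohort(n_cases = 2, n_controls = 2, axis = make_axis())
  ref <- colMeans(ds$matrix)
  chain <- vector_normalize(crop_region(emsc_correct(ds, ref, 2),
                                        1800, 1000))
  ref_c <- colMeans(crop_region(ds, 1800, 1000)$matrix)
  swapped <- vector_normalize(emsc_correct(crop_region(ds, 1800, 1000),
                                           ref_c, 2))
  expect_gt(max(abs(chain$matrix - swapped$matrix)), 1e-6)
})

test_that("EMSC inverts the generative scatter and baseline exactly", {
  # zero within-class noise: scatter + polynomial baseline only
  ds <- tiny_cohort(n_cases = 4, n_controls = 4, effect_size = 2,
                    seed = 3, patient_sd = 0, bio_sd = 0, tech_sd = 0,
                    effect_jitter_sd = 0, scatter_sd = 0.3,
                    baseline_sd = 0.1, axis = make_axis())
  prep <- serodisc:::quiet_bin(run_preprocess(ds, preprocess_config()))
  for (cl in c("cancer", "control")) {
    rows <- prep$matrix[prep$meta$class == cl, ]
    spread <- apply(rows, 2, function(v) diff(range(v)))
    expect_lt(max(spread), 1e-6)
  }
})
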