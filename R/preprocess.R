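#' Configure the preprocessing chain
#'
#' The chain applies, in fixed order: extended multiplicative signal
#' correction (EMSC), fingerprint-region selection, vector normalization
#' and spectral binning.
#'
#' @param emsc_order polynomial degree of the EMSC baseline model
#'   (0-4; default 2, i.e. offset + linear + quadratic drift).
#' @param emsc_reference `"mean-of-training"` (reference recomputed from
#'   training rows per split) or `"supplied"` (pass `reference` explicitly
#'   to [run_preprocess()]).
#' @param crop_high,crop_low fingerprint-region bounds, cm^-1 (defaults
#'   1800 and 1000).
#' @param normalization `"vector"` (per-spectrum mean-centering then unit
#'   Euclidean norm), `"l2"` (unit norm without centering) or `"none"`.
#' @param bin_factor number of adjacent points averaged per bin (default 8).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(emsc_order = 2,
                              emsc_reference = c("mean-of-training",
                                                 "supplied"),
                              crop_high = 1800, crop_low = 1000,
                              normalization = c("vector", "l2", "none"),
                              bin_factor = 8) {
  emsc_reference <- match.arg(emsc_reference)
  normalization <- match.arg(normalization)
  stopifnot(crop_high > crop_low, bin_factor >= 1, emsc_order >= 0)
  structure(list(emsc_order = as.integer(emsc_order),
                 emsc_reference = emsc_reference,
                 crop_high = crop_high, crop_low = crop_low,
                 normalization = normalization,
                 bin_factor = as.integer(bin_factor)),
            class = "preprocess_config")
}

#' Extended multiplicative signal correction
#'
#' Fits each spectrum `x` as `x = b * ref + sum_k c_k P_k(t)` by least
#' squares, where `P_k` are Legendre polynomials on the axis rescaled to
#' `[-1, 1]` (`P_0 = 1` carries the additive offset), and returns
#' `(x - sum_k c_k P_k) / b`: scatter divided out, baseline subtracted.
#' Fitted coefficients are kept as a diagnostics attribute.
#'
#' @param ds a [spectral_dataset()].
#' @param reference reference intensities on the same axis (not
#'   identically zero).
#' @param order polynomial degree (>= 0).
#' @return the corrected dataset; `attr(, "emsc_fit")` holds a matrix with
#'   one row per spectrum: `b` (reference scale) and `c0..c<order>`
#'   (polynomial coefficients; `c0` is the additive offset).
#' @export
emsc_correct <- function(ds, reference, order = 2) {
  stopifnot(inherits(ds, "spectral_dataset"), order >= 0)
  reference <- as.numeric(reference)
  if (length(reference) != n_points(ds))
    stop("emsc_correct: reference length != axis length", call. = FALSE)
  if (all(abs(reference) < 1e-12))
    stop("emsc_correct: reference is identically zero", call. = FALSE)
  P <- legendre_design(scale_axis(ds$axis), order)   # n_points x (order+1)
  D <- cbind(ref = reference, P)
  # least squares for all spectra at once via the QR of the shared design
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("emsc_correct: collinear design (reference lies in the ",
         "polynomial space)", call. = FALSE)
  R <- qr.R(qrD)
  # R' R coef = D' x_i for every spectrum: two triangular solves on a
  # (order+2)-sized system, with D'X computed as one matrix product
  DtX <- t(ds$matrix %*% D)                          # (order+2) x n_spectra
  coef <- backsolve(R, forwardsolve(t(R), DtX))
  b <- coef[1L, ]
  degenerate <- which(abs(b) < 1e-8)
  if (length(degenerate))
    stop("emsc_correct: degenerate fit (|b| < 1e-8) for spectrum row ",
         degenerate[1L], call. = FALSE)
  corrected <- (ds$matrix -
                  t(coef[-1L, , drop = FALSE]) %*% t(P)) / b
  out <- spectral_dataset(corrected, ds$axis, ds$meta, validate = FALSE)
  fit <- t(coef)
  colnames(fit) <- c("b", paste0("c", 0:order))
  attr(out, "emsc_fit") <- fit
  out
}

# Legendre polynomials P_0..P_order on t in [-1, 1] via the recurrence
legendre_design <- function(t, order) {
  P <- matrix(0, nrow = length(t), ncol = order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- t
  if (order >= 2L) {
    for (k in 2L:order) {
      P[, k + 1L] <- ((2 * k - 1) * t * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  P
}

#' Select a wavenumber region
#'
#' Retains axis points with `low <= wavenumber <= high` (inclusive),
#' preserving the high-to-low order. The defaults select the fingerprint
#' region (1800-1000 cm^-1).
#'
#' @param ds a [spectral_dataset()].
#' @param high,low region bounds, cm^-1.
#' @return the cropped dataset.
#' @export
crop_region <- function(ds, high = 1800, low = 1000) {
  stopifnot(inherits(ds, "spectral_dataset"))
  keep <- ds$axis >= low & ds$axis <= high
  if (!any(keep))
    stop("crop_region: [", low, ", ", high, "] does not overlap the axis",
         call. = FALSE)
  spectral_dataset(ds$matrix[, keep, drop = FALSE], ds$axis[keep], ds$meta,
                   validate = FALSE)
}

#' Vector-normalize each spectrum
#'
#' Subtracts each spectrum's own mean, then divides by its Euclidean norm,
#' so every row has mean 0 and L2 norm 1. Invariant to per-spectrum affine
#' intensity changes `c*x + d` with `c > 0`.
#'
#' @param ds a [spectral_dataset()].
#' @param center subtract the per-spectrum mean first (default `TRUE`; set
#'   `FALSE` for plain L2 scaling).
#' @return the normalized dataset.
#' @export
vector_normalize <- function(ds, center = TRUE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  m <- ds$matrix
  if (center) m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12))
    stop("vector_normalize: zero-variance spectrum at row ",
         which(nrm < 1e-12)[1L], call. = FALSE)
  spectral_dataset(m / nrm, ds$axis, ds$meta, validate = FALSE)
}

#' Bin adjacent spectral points
#'
#' Replaces consecutive non-overlapping groups of `factor` points by their
#' mean intensity and mean wavenumber. A trailing remainder of fewer than
#' `factor` points is dropped with a warning, so every feature averages the
#' same number of points. The mean (not the sum) keeps magnitudes
#' comparable across bin factors.
#'
#' @param ds a [spectral_dataset()].
#' @param factor points per bin (>= 1).
#' @return the binned dataset.
#' @export
bin_spectra <- function(ds, factor = 8) {
  stopifnot(inherits(ds, "spectral_dataset"))
  factor <- as.integer(factor)
  p <- n_points(ds)
  if (factor < 1L) stop("bin_spectra: factor must be >= 1", call. = FALSE)
  if (factor > p)
    stop("bin_spectra: factor (", factor, ") exceeds the ", p,
         " available points", call. = FALSE)
  if (factor == 1L) return(ds)
  n_bins <- p %/% factor
  dropped <- p - n_bins * factor
  if (dropped > 0L)
    warning(warningCondition(
      paste0("bin_spectra: dropping trailing remainder of ", dropped,
             " point(s)"),
      class = "serodisc_bin_remainder"))
  idx <- seq_len(n_bins * factor)
  grp <- rep(seq_len(n_bins), each = factor)
  # row-wise group means via matrix multiplication with an averaging map
  A <- matrix(0, nrow = n_bins * factor, ncol = n_bins)
  A[cbind(idx, grp)] <- 1 / factor
  spectral_dataset(ds$matrix[, idx, drop = FALSE] %*% A,
                   drop(ds$axis[idx] %*% A), ds$meta, validate = FALSE)
}

#' Run the full preprocessing chain
#'
#' Applies EMSC -> crop -> normalization -> binning in exactly that order.
#' With `emsc_reference = "mean-of-training"` the EMSC reference is the
#' mean raw spectrum of the rows flagged as training, then applied to all
#' rows — the reference never sees test data.
#'
#' @param ds a [spectral_dataset()].
#' @param cfg a [preprocess_config()].
#' @param reference explicit reference intensities (required when
#'   `cfg$emsc_reference == "supplied"`).
#' @param train_rows logical or integer index of training rows used to
#'   compute the mean reference; default all rows.
#' @return the preprocessed dataset.
#' @export
run_preprocess <- function(ds, cfg = preprocess_config(), reference = NULL,
                           train_rows = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"),
            inherits(cfg, "preprocess_config"))
  if (cfg$emsc_reference == "supplied") {
    if (is.null(reference))
      stop("run_preprocess: cfg requests a supplied reference but none ",
           "was given", call. = FALSE)
  } else {
    rows <- if (is.null(train_rows)) seq_len(n_spectra(ds)) else train_rows
    reference <- colMeans(ds$matrix[rows, , drop = FALSE])
  }
  out <- emsc_correct(ds, reference, cfg$emsc_order)
  out <- crop_region(out, cfg$crop_high, cfg$crop_low)
  if (cfg$normalization != "none")
    out <- vector_normalize(out, center = cfg$normalization == "vector")
  if (cfg$bin_factor > 1L)
    out <- bin_spectra(out, cfg$bin_factor)
  out
}
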