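#' Assemble a spectral dataset
#'
#' The universal container passed between pipeline stages: a spectra matrix,
#' a shared wavenumber axis and per-spectrum metadata describing the nested
#' replicate structure (patient, biological replicate, technical replicate).
#'
#' @param matrix numeric matrix, one row per spectrum, one column per
#'   wavenumber (absorbance, arbitrary units).
#' @param axis numeric vector of wavenumbers in cm^-1, strictly decreasing
#'   (stored high-to-low, matching the conventional 4000 -> 450 presentation).
#' @param meta data.frame with columns `patient_id` (character), `class`
#'   (one of `"cancer"`, `"control"`; cancer is the positive class
#'   throughout), `bio_rep` and `tech_rep` (integer replicate indices).
#' @param validate logical; check invariants (default `TRUE`).
#'
#' @return An object of class `spectral_dataset`: a list with elements
#'   `matrix`, `axis`, `meta`.
#' @export
spectral_dataset <- function(matrix, axis, meta, validate = TRUE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  dimnames(matrix) <- NULL
  axis <- as.numeric(axis)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  meta$patient_id <- as.character(meta$patient_id)
  meta$class <- as.character(meta$class)
  meta$bio_rep <- as.integer(meta$bio_rep)
  meta$tech_rep <- as.integer(meta$tech_rep)
  ds <- structure(list(matrix = matrix, axis = axis, meta = meta),
                  class = "spectral_dataset")
  if (validate) validate_dataset(ds)
  ds
}

#' Validate a spectral dataset's invariants
#'
#' Checks dimensional consistency, strict high-to-low axis ordering,
#' finiteness of all intensities, metadata completeness and uniqueness of
#' every (patient, biological replicate, technical replicate) triple.
#'
#' @param ds a [spectral_dataset()].
#' @param require_two_classes require both class labels present (needed for
#'   any classification use).
#' @return `ds`, invisibly. Errors describe the first violated invariant.
#' @export
validate_dataset <- function(ds, require_two_classes = FALSE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (length(ds$axis) < 2L)
    stop("axis must contain at least 2 wavenumbers", call. = FALSE)
  if (ncol(ds$matrix) != length(ds$axis))
    stop("matrix has ", ncol(ds$matrix), " columns but axis has ",
         length(ds$axis), " points", call. = FALSE)
  if (any(diff(ds$axis) >= 0))
    stop("wavenumber axis must be strictly decreasing (high -> low)",
         call. = FALSE)
  if (!all(is.finite(ds$matrix))) {
    bad <- which(!apply(is.finite(ds$matrix), 1L, all))[1L]
    stop("non-finite intensity in spectrum row ", bad, call. = FALSE)
  }
  need <- c("patient_id", "class", "bio_rep", "tech_rep")
  miss <- setdiff(need, names(ds$meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(ds$meta) != nrow(ds$matrix))
    stop("metadata rows (", nrow(ds$meta), ") != spectra rows (",
         nrow(ds$matrix), ")", call. = FALSE)
  if (!all(ds$meta$class %in% c("cancer", "control")))
    stop("class labels must be 'cancer' or 'control'", call. = FALSE)
  key <- paste(ds$meta$patient_id, ds$meta$bio_rep, ds$meta$tech_rep,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (patient_id, bio_rep, tech_rep) triple at row ",
         which(duplicated(key))[1L], call. = FALSE)
  cls <- class_per_patient(ds$meta)
  if (anyNA(cls))
    stop("a patient carries more than one class label", call. = FALSE)
  if (require_two_classes && length(unique(ds$meta$class)) < 2L)
    stop("dataset must contain both classes", call. = FALSE)
  invisible(ds)
}

# one class label per patient; NA where a patient is inconsistent
class_per_patient <- function(meta) {
  tab <- unique(meta[, c("patient_id", "class")])
  if (anyDuplicated(tab$patient_id)) {
    dup <- unique(tab$patient_id[duplicated(tab$patient_id)])
    out <- stats::setNames(tab$class, tab$patient_id)
    out[dup] <- NA_character_
    return(out)
  }
  stats::setNames(tab$class, tab$patient_id)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d spectra x %d points | axis %.1f -> %.1f cm-1\n",
    nrow(x$matrix), length(x$axis), max(x$axis), min(x$axis)))
  np <- length(unique(x$meta$patient_id))
  tab <- table(class_per_patient(x$meta))
  cat(sprintf("  %d patients (%s)\n", np,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Number of spectra / spectral points in a dataset
#' @param ds a [spectral_dataset()].
#' @return integer count.
#' @export
n_spectra <- function(ds) nrow(ds$matrix)

#' @rdname n_spectra
#' @export
n_points <- function(ds) length(ds$axis)

#' Subset a spectral dataset by row
#' @param ds a [spectral_dataset()].
#' @param rows integer or logical row index.
#' @return the subsetted `spectral_dataset` (axis unchanged).
#' @export
subset_rows <- function(ds, rows) {
  spectral_dataset(ds$matrix[rows, , drop = FALSE], ds$axis,
                   ds$meta[rows, , drop = FALSE], validate = FALSE)
}

# internal: 0/1 coding, cancer (positive class) = 1
class_to_numeric <- function(class) as.integer(class == "cancer")
numeric_to_class <- function(z) ifelse(z >= 1L, "cancer", "control")
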