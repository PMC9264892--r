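#' Permutation-null validation of a classification pipeline
#'
#' Per iteration: a fresh patient-grouped split; an observed model trained
#' on the true labels gives a patient-consensus test accuracy; a null model
#' trained after permuting class labels across patients (all nine spectra
#' of a patient keep one common permuted label, so class counts are
#' preserved exactly) gives a null accuracy against those permuted labels.
#'
#' The p-value is the add-one exceedance of the null distribution against a
#' single observed accuracy (the first iteration's):
#' `p = (1 + #\{null_i >= obs_1\}) / (n_iter + 1)`. Under exchangeability
#' this is the classic permutation estimator — never zero, uniformly
#' distributed when no class effect exists — while the full observed
#' distribution over all iterations is retained for the two-histogram
#' presentation. Hyperparameters are tuned once on the first split and
#' reused across iterations unless `retune = TRUE`.
#'
#' @param ds a [spectral_dataset()].
#' @param spec a [model_spec()] (default PLS-DA, the customary family for
#'   this validation).
#' @param prep_cfg a [preprocess_config()].
#' @param n_iter number of iterations (default 1000, minimum 100 unless
#'   `allow_small = TRUE`).
#' @param sampling `"none"` or `"smote"` (training rows only, both arms).
#' @param base_seed integer seed; iteration `i` uses `base_seed + i`.
#' @param train_frac training fraction.
#' @param retune re-tune hyperparameters inside every iteration.
#' @param allow_small permit `n_iter < 100` (tiny illustrative runs).
#' @return a `permutation_result`: list with `observed_acc`, `null_acc`
#'   (each length `n_iter`), `p_value`, `p_floor` (`1/(n_iter+1)`),
#'   `n_iter`, `family`.
#' @export
permutation_test <- function(ds, spec = model_spec("plsda"),
                             prep_cfg = preprocess_config(),
                             n_iter = 1000, sampling = c("none", "smote"),
                             base_seed = 1L, train_frac = 0.7,
                             retune = FALSE, allow_small = FALSE) {
  sampling <- match.arg(sampling)
  if (n_iter < 100 && !allow_small)
    stop("permutation_test: n_iter must be >= 100", call. = FALSE)
  validate_dataset(ds, require_two_classes = TRUE)
  cls <- class_per_patient(ds$meta)
  patients <- names(cls)
  tuned <- NULL
  observed <- numeric(n_iter)
  null_acc <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    seed_i <- as.integer(base_seed) + i
    # the split and preprocessing are label-free: shared by both arms
    plan <- split_by_patient(ds, train_frac, seed = seed_i)
    tr_rows <- ds$meta$patient_id %in% plan$train_patients
    prep <- quiet_bin(run_preprocess(ds, prep_cfg, train_rows = tr_rows))
    # observed arm
    obs <- fit_eval_split(prep$matrix, ds$meta$class, ds$meta$patient_id,
                          tr_rows, spec, sampling, seed_i,
                          tuned = if (retune) NULL else tuned)
    if (is.null(tuned)) tuned <- obs$tuned
    observed[i] <- obs$accuracy
    # null arm: permute the patient -> class map, spectra follow patients
    set.seed(seed_i + 499979L)
    perm_cls <- stats::setNames(sample(unname(cls)), patients)
    stopifnot(identical(as.vector(sort(table(perm_cls))),
                        as.vector(sort(table(cls)))))
    nul <- fit_eval_split(prep$matrix,
                          unname(perm_cls[ds$meta$patient_id]),
                          ds$meta$patient_id, tr_rows, spec, sampling,
                          seed_i, tuned = if (retune) NULL else tuned)
    null_acc[i] <- nul$accuracy
  }
  p_floor <- 1 / (n_iter + 1)
  p <- (1 + sum(null_acc >= observed[1L])) / (n_iter + 1)
  structure(list(observed_acc = observed, null_acc = null_acc,
                 p_value = p, p_floor = p_floor,
                 n_iter = as.integer(n_iter), family = spec$family),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s, %d iterations\n", x$family, x$n_iter))
  cat(sprintf("  observed accuracy %.3f +/- %.3f | null %.3f +/- %.3f\n",
              mean(x$observed_acc), stats::sd(x$observed_acc),
              mean(x$null_acc), stats::sd(x$null_acc)))
  cat(if (x$p_value <= x$p_floor)
        sprintf("  p < %.4g (floor)\n", x$p_floor)
      else sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

# one labelled split on precomputed features -> patient-consensus accuracy
fit_eval_split <- function(X, class, pid_all, tr_rows, spec, sampling,
                           seed, tuned = NULL) {
  y <- class_to_numeric(class)
  Xtr <- X[tr_rows, , drop = FALSE]
  ytr <- y[tr_rows]
  groups <- pid_all[tr_rows]
  if (sampling == "smote") {
    sm <- smote(Xtr, ytr, seed = seed)
    Xtr <- sm$X
    ytr <- sm$y
    groups <- c(groups, sprintf("synthetic_%04d", seq_len(sum(sm$synthetic))))
  }
  if (is.null(tuned))
    tuned <- tune_cv(Xtr, ytr, spec, seed = seed, groups = groups)
  model <- fit_model(Xtr, ytr, tuned, seed = seed)
  te_rows <- which(!tr_rows)
  scores <- predict_scores(model, X[te_rows, , drop = FALSE])
  labels <- ifelse(scores >= model$threshold, "cancer", "control")
  pid <- pid_all[te_rows]
  truth <- stats::setNames(class[te_rows], pid)
  patients <- unique(pid)
  cons <- vapply(patients, function(p) {
    sel <- pid == p
    consensus(labels[sel], mean_score = mean(scores[sel]),
              threshold = model$threshold)
  }, character(1))
  list(accuracy = mean(cons == unname(truth[patients])), tuned = tuned)
}

#' Gini importance profile over binned wavenumbers
#'
#' Averages random-forest mean-decrease-in-Gini importances over repeats
#' and maps them to the bin-centre wavenumbers, with a ranked top-k table.
#' Equal importances rank in ascending wavenumber order (documented tie
#' rule).
#'
#' @param importance numeric matrix, repeats x features (one RF per row),
#'   or a `repeat_summary` from an RF [run_repeats()] run.
#' @param feature_axis bin-centre wavenumbers, cm^-1 (taken from the
#'   summary when one is supplied).
#' @param top_k rows of the ranked table (default 15).
#' @param normalize rescale mean importances to sum to 1.
#' @return a `gini_profile`: list with `wavenumber`, `importance` (mean per
#'   bin), `top` (data.frame rank/wavenumber/importance), `n_repeats`.
#' @export
gini_profile <- function(importance, feature_axis = NULL, top_k = 15,
                         normalize = FALSE) {
  if (inherits(importance, "repeat_summary")) {
    if (is.null(importance$importance))
      stop("gini_profile: summary holds no importances (not an RF run)",
           call. = FALSE)
    feature_axis <- importance$feature_axis
    importance <- importance$importance
  }
  importance <- as.matrix(importance)
  if (is.null(feature_axis) || length(feature_axis) != ncol(importance))
    stop("gini_profile: feature_axis length must match the feature count",
         call. = FALSE)
  prof <- colMeans(importance)
  if (normalize) prof <- prof / sum(prof)
  ord <- order(-prof, feature_axis)
  k <- min(top_k, length(prof))
  structure(list(wavenumber = feature_axis, importance = prof,
                 top = data.frame(rank = seq_len(k),
                                  wavenumber = feature_axis[ord[seq_len(k)]],
                                  importance = prof[ord[seq_len(k)]],
                                  row.names = NULL),
                 n_repeats = nrow(importance)),
            class = "gini_profile")
}

#' @export
print.gini_profile <- function(x, ...) {
  cat(sprintf("<gini_profile> %d bins, %d repeat(s); top bin %.0f cm-1\n",
              length(x$wavenumber), x$n_repeats, x$top$wavenumber[1L]))
  invisible(x)
}

#' Write evaluation figures and tables
#'
#' Renders the standard output set: ROC curve with the shaded constraint
#' region and labelled A/B/C operating points; overlaid null/observed
#' accuracy histograms; Gini importance trace with the mean class spectra
#' overlaid; and a metrics summary table. File names are deterministic;
#' a missing permutation result skips that figure with a message.
#'
#' @param summary a `repeat_summary` (or list of them, one per family).
#' @param roc a `roc_curve` used for the ROC figure (default: the first
#'   summary's pooled ROC).
#' @param perm a `permutation_result`, or `NULL` to skip.
#' @param gini a `gini_profile`, or `NULL` to skip.
#' @param outdir output directory (created if needed).
#' @param floor operating-point constraint floor for the ROC figure.
#' @param mean_spectra optional data.frame (`wavenumber`, `cancer`,
#'   `control`) overlaid on the Gini trace.
#' @return character vector of files written, invisibly.
#' @export
render_reports <- function(summary, roc = NULL, perm = NULL, gini = NULL,
                           outdir, floor = 0.60, mean_spectra = NULL) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("render_reports: cannot create output directory '", outdir, "'",
         call. = FALSE)
  summaries <- if (inherits(summary, "repeat_summary")) list(summary)
               else summary
  files <- character(0)

  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(family = s$family, sampling = s$sampling,
               n_repeats = s$n_repeats,
               metric = s$aggregate$metric, mean = s$aggregate$mean,
               sd = s$aggregate$sd, pooled_auc = s$roc$auc)
  }))
  f <- file.path(outdir, "metrics_summary.csv")
  data.table::fwrite(tab, f)
  files <- c(files, f)

  if (is.null(roc)) roc <- summaries[[1L]]$roc
  ops <- operating_points(roc, floor)
  roc_df <- data.frame(fpr = 1 - roc$specificity, tpr = roc$sensitivity)
  g <- ggplot2::ggplot(roc_df, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 1 - floor, ymin = floor,
                      ymax = 1, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("Pooled ROC (AUC = %.3f)", roc$auc))
  if (!ops$empty)
    g <- g + ggplot2::geom_point(
      data = data.frame(fpr = 1 - ops$points$specificity,
                        tpr = ops$points$sensitivity),
      colour = "darkorange", size = 2.5) +
      ggplot2::geom_text(
        data = data.frame(fpr = 1 - ops$points$specificity,
                          tpr = ops$points$sensitivity,
                          lab = ops$points$point),
        ggplot2::aes(label = lab), nudge_x = 0.04, nudge_y = -0.03)
  f <- file.path(outdir, "roc_curve.png")
  ggplot2::ggsave(f, g, width = 5, height = 5, dpi = 150)
  files <- c(files, f)

  if (!is.null(perm)) {
    pd <- rbind(data.frame(accuracy = perm$observed_acc, model = "observed"),
                data.frame(accuracy = perm$null_acc, model = "null"))
    g <- ggplot2::ggplot(pd, ggplot2::aes(x = accuracy, fill = model)) +
      ggplot2::geom_histogram(alpha = 0.6, position = "identity",
                              bins = 30) +
      ggplot2::scale_fill_manual(values = c(observed = "steelblue",
                                            null = "firebrick")) +
      ggplot2::labs(x = "Patient-level accuracy", y = "Count",
                    title = sprintf("Permutation validation (p %s %.4g)",
                                    if (perm$p_value <= perm$p_floor)
                                      "<" else "=",
                                    max(perm$p_value, perm$p_floor)))
    f <- file.path(outdir, "permutation_hist.png")
    ggplot2::ggsave(f, g, width = 6, height = 4, dpi = 150)
    files <- c(files, f)
  } else {
    message("render_reports: no permutation result; histogram skipped")
  }

  if (!is.null(gini)) {
    gd <- data.frame(wavenumber = gini$wavenumber,
                     importance = gini$importance)
    g <- ggplot2::ggplot(gd, ggplot2::aes(x = wavenumber, y = importance)) +
      ggplot2::geom_line(colour = "darkgreen") +
      ggplot2::geom_point(data = gd[gd$wavenumber %in%
                                      gini$top$wavenumber[1:3], ],
                          colour = "darkorange", size = 2) +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = "Wavenumber (cm-1)", y = "Mean Gini importance",
                    title = "Random-forest importance profile")
    if (!is.null(mean_spectra)) {
      sc <- max(gd$importance) /
        max(abs(c(mean_spectra$cancer, mean_spectra$control)))
      g <- g +
        ggplot2::geom_line(data = mean_spectra,
                           ggplot2::aes(y = cancer * sc),
                           colour = "firebrick", alpha = 0.5) +
        ggplot2::geom_line(data = mean_spectra,
                           ggplot2::aes(y = control * sc),
                           colour = "steelblue", alpha = 0.5)
    }
    f <- file.path(outdir, "gini_importance.png")
    ggplot2::ggsave(f, g, width = 6, height = 4, dpi = 150)
    files <- c(files, f)
  }
  invisible(files)
}
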