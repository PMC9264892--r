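#' Patient-grouped stratified train/test split
#'
#' Assigns whole patients (all their spectra) to train or test, stratified
#' by class: `round(train_frac * n)` patients of each class go to training.
#' No patient can appear on both sides.
#'
#' @param ds a [spectral_dataset()].
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @param repeat_index stored in the plan for bookkeeping.
#' @return a `split_plan`: list with `train_patients`, `test_patients`,
#'   `seed`, `repeat_index`.
#' @export
split_by_patient <- function(ds, train_frac = 0.7, seed = 1L,
                             repeat_index = 1L) {
  cls <- class_per_patient(ds$meta)
  tab <- table(cls)
  if (length(tab) < 2L || any(tab < 2L))
    stop("split_by_patient: need at least 2 patients in each class",
         call. = FALSE)
  set.seed(as.integer(seed))
  train <- character(0)
  for (cl in names(tab)) {
    ids <- names(cls)[cls == cl]
    n_tr <- round(train_frac * length(ids))
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L)  # both sides non-empty
    train <- c(train, sample(ids, n_tr))
  }
  structure(list(train_patients = sort(train),
                 test_patients = sort(setdiff(names(cls), train)),
                 seed = as.integer(seed),
                 repeat_index = as.integer(repeat_index)),
            class = "split_plan")
}

#' Majority-vote consensus over replicate predictions
#'
#' The patient-level diagnosis is the majority of the patient's
#' spectrum-level predictions; an odd vote count (nine replicates) makes
#' ties impossible.
#'
#' @param votes character vector of `"cancer"`/`"control"` labels.
#' @param mean_score optional mean continuous score used as fallback when
#'   an even vote count ties (score above the family threshold
#'   reads as cancer); without it an even count is an error.
#' @param threshold score threshold for the fallback.
#' @return a single label.
#' @export
consensus <- function(votes, mean_score = NULL, threshold = 0.5) {
  stopifnot(all(votes %in% c("cancer", "control")))
  n_cancer <- sum(votes == "cancer")
  n_control <- length(votes) - n_cancer
  if (n_cancer == n_control) {
    if (is.null(mean_score))
      stop("consensus: even vote count can tie; supply mean_score or use ",
           "an odd replicate count", call. = FALSE)
    return(if (mean_score >= threshold) "cancer" else "control")
  }
  if (n_cancer > n_control) "cancer" else "control"
}

#' Patient-level sensitivity, specificity and accuracy
#'
#' Cancer is the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n.
#'
#' @param truth,pred character vectors of `"cancer"`/`"control"` labels.
#' @return named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
classification_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(unique(truth)) < 2L)
    stop("classification_metrics: truth contains a single class",
         call. = FALSE)
  tp <- sum(truth == "cancer" & pred == "cancer")
  fn <- sum(truth == "cancer" & pred == "control")
  tn <- sum(truth == "control" & pred == "control")
  fp <- sum(truth == "control" & pred == "cancer")
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(truth))
}

#' Empirical ROC curve from continuous scores
#'
#' Sweeps a threshold over the pooled scores (equal scores collapse to one
#' threshold step) with cancer as the positive class; AUC by the trapezoid
#' rule, which equals the pairwise concordance estimator
#' `P(s_case > s_ctrl) + 0.5 P(tie)` exactly.
#'
#' @param scores numeric scores, larger = more cancer-like.
#' @param labels `"cancer"`/`"control"` (or 0/1) per score.
#' @return a `roc_curve`: data.frame-backed list with `thresholds`,
#'   `sensitivity`, `specificity` (endpoints (1,0) and (0,1) included) and
#'   `auc`.
#' @export
pooled_roc <- function(scores, labels) {
  y <- coerce_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("pooled_roc: need at least one case and one control",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # collapse tied scores into single threshold steps
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(yy)[last_of_tie]
  fp <- cumsum(1L - yy)[last_of_tie]
  sens <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  thr <- c(Inf, s[last_of_tie], -Inf)
  auc <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens,
                 specificity = 1 - fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d threshold steps, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Constrained ROC operating points
#'
#' Within the region where both sensitivity and specificity are at least
#' `floor`, reports point A (maximum sensitivity), point B (maximum
#' specificity) and point C (most balanced: minimum |sens - spec|, ties to
#' the larger sens + spec). Boundary points are admitted; an empty region
#' is reported as such.
#'
#' @param roc a `roc_curve`.
#' @param floor minimum sensitivity and specificity, in (0, 1)
#'   (e.g. 0.60 or 0.45).
#' @return list with `floor`, `empty`, and data.frame `points`
#'   (rows A, B, C with threshold, sensitivity, specificity).
#' @export
operating_points <- function(roc, floor = 0.60) {
  stopifnot(inherits(roc, "roc_curve"), floor > 0, floor < 1)
  ok <- roc$sensitivity >= floor & roc$specificity >= floor
  if (!any(ok))
    return(list(floor = floor, empty = TRUE,
                points = data.frame(point = character(0),
                                    threshold = numeric(0),
                                    sensitivity = numeric(0),
                                    specificity = numeric(0))))
  sens <- roc$sensitivity[ok]
  spec <- roc$specificity[ok]
  thr <- roc$thresholds[ok]
  pick <- function(o) o[1L]
  iA <- pick(order(-sens, -spec))
  iB <- pick(order(-spec, -sens))
  iC <- pick(order(abs(sens - spec), -(sens + spec)))
  idx <- c(A = iA, B = iB, C = iC)
  list(floor = floor, empty = FALSE,
       points = data.frame(point = names(idx), threshold = thr[idx],
                           sensitivity = sens[idx], specificity = spec[idx],
                           row.names = NULL))
}

#' Repeated patient-grouped evaluation of one classifier family
#'
#' The study's evaluation engine. Per repeat: patient-grouped stratified
#' 70/30 split -> EMSC reference from training rows only -> full
#' preprocessing of all rows -> optional SMOTE on the training features ->
#' grouped 5-fold CV tuning -> refit on all training data -> spectrum-level
#' scores on the test set -> per-patient majority consensus and mean score
#' -> patient-level metrics. Metrics are aggregated as mean and SD over
#' repeats; per-patient test scores are pooled across repeats for
#' [pooled_roc()]. Repeat `r` uses seed `base_seed + r`, so any single
#' repeat is reproducible in isolation.
#'
#' @param ds a [spectral_dataset()] (raw, unpreprocessed).
#' @param spec a [model_spec()].
#' @param prep_cfg a [preprocess_config()].
#' @param n_repeats number of independent splits (default 51).
#' @param sampling `"none"` or `"smote"` (training rows only).
#' @param base_seed integer base seed.
#' @param train_frac training fraction (default 0.7).
#' @param cv_folds folds for hyperparameter tuning (default 5).
#' @param reference explicit EMSC reference when
#'   `prep_cfg$emsc_reference == "supplied"`.
#' @return a `repeat_summary`: list with `per_repeat` (data.frame of
#'   per-repeat sensitivity/specificity/accuracy/AUC and tuned value),
#'   `aggregate` (mean and SD per metric), `pooled` (per test appearance:
#'   patient, repeat, truth, consensus, mean score), `roc` (pooled ROC),
#'   `importance` (RF only: repeats x features Gini matrix), `feature_axis`
#'   (bin-centre wavenumbers), `family`, `sampling`, `n_repeats`.
#' @export
run_repeats <- function(ds, spec, prep_cfg = preprocess_config(),
                        n_repeats = 51, sampling = c("none", "smote"),
                        base_seed = 1L, train_frac = 0.7, cv_folds = 5,
                        reference = NULL) {
  sampling <- match.arg(sampling)
  validate_dataset(ds, require_two_classes = TRUE)
  per <- vector("list", n_repeats)
  pooled <- vector("list", n_repeats)
  imp <- vector("list", n_repeats)
  feature_axis <- NULL
  for (r in seq_len(n_repeats)) {
    seed_r <- as.integer(base_seed) + r
    res <- run_single_repeat(ds, spec, prep_cfg, sampling, seed_r,
                             train_frac, cv_folds, reference, r)
    per[[r]] <- res$metrics
    pooled[[r]] <- res$pooled
    imp[[r]] <- res$importance
    feature_axis <- res$feature_axis
  }
  per_repeat <- do.call(rbind, per)
  pooled <- do.call(rbind, pooled)
  roc <- pooled_roc(pooled$mean_score, pooled$truth)
  metr <- c("sensitivity", "specificity", "accuracy", "auc")
  aggregate <- data.frame(
    metric = metr,
    mean = vapply(metr, function(m) mean(per_repeat[[m]]), numeric(1)),
    sd = vapply(metr, function(m) stats::sd(per_repeat[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(per_repeat = per_repeat, aggregate = aggregate,
                 pooled = pooled, roc = roc,
                 importance = if (spec$family == "rf")
                   do.call(rbind, imp) else NULL,
                 feature_axis = feature_axis,
                 family = spec$family, sampling = sampling,
                 n_repeats = as.integer(n_repeats)),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("<repeat_summary> %s, %d repeats, sampling = %s\n",
              x$family, x$n_repeats, x$sampling))
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-11s %.3f +/- %.3f\n", a$metric[i], a$mean[i], a$sd[i]))
  cat(sprintf("  pooled AUC  %.3f\n", x$roc$auc))
  invisible(x)
}

# one split -> preprocess -> (smote) -> tune -> fit -> consensus -> metrics
run_single_repeat <- function(ds, spec, prep_cfg, sampling, seed_r,
                              train_frac, cv_folds, reference, repeat_index) {
  plan <- split_by_patient(ds, train_frac, seed = seed_r,
                           repeat_index = repeat_index)
  tr_rows <- ds$meta$patient_id %in% plan$train_patients
  prep <- quiet_bin(run_preprocess(ds, prep_cfg, reference = reference,
                                   train_rows = tr_rows))
  X <- prep$matrix
  y <- class_to_numeric(ds$meta$class)
  Xtr <- X[tr_rows, , drop = FALSE]
  ytr <- y[tr_rows]
  groups <- ds$meta$patient_id[tr_rows]
  if (sampling == "smote") {
    sm <- smote(Xtr, ytr, seed = seed_r)
    Xtr <- sm$X
    ytr <- sm$y
    # synthetic rows are their own singleton groups for fold assignment
    groups <- c(groups, sprintf("synthetic_%04d", seq_len(sum(sm$synthetic))))
  }
  tuned <- tune_cv(Xtr, ytr, spec, folds = cv_folds, seed = seed_r,
                   groups = groups)
  model <- fit_model(Xtr, ytr, tuned, seed = seed_r)
  te_rows <- which(!tr_rows)
  scores <- predict_scores(model, X[te_rows, , drop = FALSE])
  labels <- ifelse(scores >= model$threshold, "cancer", "control")
  pid <- ds$meta$patient_id[te_rows]
  cls <- class_per_patient(ds$meta[te_rows, , drop = FALSE])
  patients <- unique(pid)
  cons <- character(length(patients))
  mscore <- numeric(length(patients))
  for (i in seq_along(patients)) {
    sel <- pid == patients[i]
    mscore[i] <- mean(scores[sel])
    cons[i] <- consensus(labels[sel], mean_score = mscore[i],
                         threshold = model$threshold)
  }
  truth <- unname(cls[patients])
  m <- classification_metrics(truth, cons)
  auc <- pooled_roc(mscore, truth)$auc
  tuned_val <- tuned$tuned[[1L]]
  list(metrics = data.frame(repeat_index = repeat_index,
                            sensitivity = m[["sensitivity"]],
                            specificity = m[["specificity"]],
                            accuracy = m[["accuracy"]], auc = auc,
                            tuned = tuned_val),
       pooled = data.frame(repeat_index = repeat_index,
                           patient_id = patients, truth = truth,
                           consensus = cons, mean_score = mscore,
                           stringsAsFactors = FALSE),
       importance = if (spec$family == "rf")
         model$parameters$importance else NULL,
       feature_axis = prep$axis)
}

# muffle only the expected trailing-remainder binning note inside loops
quiet_bin <- function(expr) {
  withCallingHandlers(expr,
    serodisc_bin_remainder = function(w) invokeRestart("muffleWarning"))
}
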