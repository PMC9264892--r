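#' Describe a classifier family and its tuning grid
#'
#' The three families share one contract: [fit_model()] returns a
#' `fitted_model` whose continuous score is oriented so that larger means
#' more cancer-like, and [predict_scores()] / [predict_labels()] work
#' identically for all of them.
#'
#' @param family `"plsda"`, `"rf"` or `"svm_linear"`.
#' @param grid named list of hyperparameter candidates. Defaults:
#'   PLS-DA `n_latent` 1-15; RF `mtry` \{round(sqrt(p)), p/4, p/2\} resolved
#'   at fit time with `n_trees` fixed at 500; SVM `cost`
#'   \{0.01, 0.1, 1, 10, 100\}. Candidates are ordered simple to complex;
#'   cross-validation ties break toward the earlier (simpler) candidate.
#' @param n_trees number of trees for `family = "rf"`.
#' @return a `model_spec` list with fields `family`, `grid`, `n_trees`,
#'   `tuned` (`NULL` until [tune_cv()]).
#' @export
model_spec <- function(family = c("plsda", "rf", "svm_linear"),
                       grid = NULL, n_trees = 500) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      plsda = list(n_latent = 1:15),
      rf = list(mtry = NULL),  # resolved from feature count at tune time
      svm_linear = list(cost = c(0.01, 0.1, 1, 10, 100)))
  }
  if (length(grid) != 1L)
    stop("model_spec: grid must hold exactly one hyperparameter",
         call. = FALSE)
  if (!length(grid[[1L]]) && !(family == "rf" && is.null(grid$mtry)))
    stop("model_spec: empty hyperparameter grid", call. = FALSE)
  structure(list(family = family, grid = grid, n_trees = as.integer(n_trees),
                 tuned = NULL),
            class = "model_spec")
}

default_mtry_grid <- function(p) {
  unique(pmax(1L, c(round(sqrt(p)), floor(p / 4), floor(p / 2))))
}

#' Fit a PLS-DA model
#'
#' PLS1 regression of the 0/1 class indicator (cancer = 1) on the feature
#' matrix via the NIPALS deflation algorithm; successive score vectors are
#' mutually orthogonal. The continuous score is the predicted response; the
#' default label threshold is 0.5.
#'
#' @param X numeric feature matrix (rows = spectra).
#' @param y labels: 0/1 numeric or `"cancer"`/`"control"` character.
#' @param n_latent number of latent variables
#'   (`<= min(n_samples - 1, n_features)`).
#' @return a `fitted_model`.
#' @export
fit_plsda <- function(X, y, n_latent) {
  X <- as.matrix(X)
  y <- coerce_labels(y)
  if (length(unique(y)) < 2L)
    stop("fit_plsda: single-class response", call. = FALSE)
  if (n_latent > min(nrow(X) - 1L, ncol(X)))
    stop("fit_plsda: n_latent exceeds min(n_samples - 1, n_features)",
         call. = FALSE)
  mx <- colMeans(X)
  my <- mean(y)
  E <- sweep(X, 2L, mx)
  f <- y - my
  p <- ncol(X)
  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  Tm <- matrix(0, nrow(X), n_latent)
  qv <- numeric(n_latent)
  for (a in seq_len(n_latent)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12)
      stop("fit_plsda: response deflated to zero before component ", a,
           " (reduce n_latent)", call. = FALSE)
    w <- w / wn
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q_ <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - t_ * q_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; qv[a] <- q_
  }
  # regression coefficients in original (centered) feature space
  B <- W %*% solve(crossprod(P, W), qv)
  new_fitted_model("plsda",
                   list(B = B, mx = mx, my = my, n_latent = n_latent,
                        scores = Tm),
                   score_fun = function(par, Xn) {
                     drop(sweep(as.matrix(Xn), 2L, par$mx) %*% par$B) + par$my
                   },
                   threshold = 0.5)
}

#' Fit a random forest
#'
#' Bagged CART ensemble with the Gini split criterion (via \pkg{ranger});
#' the score is the fraction of trees voting cancer and the per-feature
#' mean decrease in Gini impurity is retained in
#' `model$parameters$importance`.
#'
#' @param X feature matrix.
#' @param y labels (0/1 or `"cancer"`/`"control"`).
#' @param mtry features tried per split (`<= ncol(X)`).
#' @param n_trees ensemble size (default 500).
#' @param seed integer seed; fixed seed gives an identical forest.
#' @param bootstrap sample with replacement (default `TRUE`; `FALSE` uses
#'   every row in every tree).
#' @return a `fitted_model`.
#' @export
fit_rf <- function(X, y, mtry, n_trees = 500, seed = 1L, bootstrap = TRUE) {
  X <- as.matrix(X)
  y <- coerce_labels(y)
  if (mtry > ncol(X))
    stop("fit_rf: mtry (", mtry, ") exceeds feature count (", ncol(X), ")",
         call. = FALSE)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- factor(numeric_to_class(y), levels = c("control", "cancer"))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = as.integer(n_trees), mtry = as.integer(mtry),
    importance = "impurity", seed = as.integer(seed),
    replace = bootstrap, sample.fraction = 1,
    num.threads = 1L)
  new_fitted_model("rf",
                   list(forest = fit, importance = unname(fit$variable.importance),
                        mtry = as.integer(mtry), n_trees = as.integer(n_trees),
                        seed = as.integer(seed)),
                   score_fun = function(par, Xn) {
                     nd <- as.data.frame(as.matrix(Xn))
                     names(nd) <- paste0("f", seq_len(ncol(nd)))
                     pr <- stats::predict(par$forest, data = nd,
                                          predict.all = TRUE,
                                          num.threads = 1L)$predictions
                     # per-tree factor codes: 1 = control, 2 = cancer
                     unname(rowMeans(pr == 2L))
                   },
                   threshold = 0.5)
}

#' Fit a linear soft-margin SVM
#'
#' Wraps \pkg{e1071}; features are not rescaled (the spectra are already
#' normalized upstream). The score is the signed distance to the separating
#' hyperplane, oriented positive toward cancer.
#'
#' @param X feature matrix.
#' @param y labels (0/1 or `"cancer"`/`"control"`).
#' @param cost soft-margin cost parameter (> 0).
#' @return a `fitted_model`.
#' @export
fit_svm_linear <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X)))
    stop("fit_svm_linear: non-finite feature values", call. = FALSE)
  y <- coerce_labels(y)
  if (length(unique(y)) < 2L)
    stop("fit_svm_linear: single-class response", call. = FALSE)
  stopifnot(cost > 0)
  yf <- factor(numeric_to_class(y), levels = c("control", "cancer"))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE)
  # e1071 orients decision values toward the first class seen in training;
  # establish the sign that points toward cancer once, on the training data
  dv <- drop(attr(stats::predict(fit, X, decision.values = TRUE),
                  "decision.values"))
  flip <- if (mean(dv[y == 1L]) >= mean(dv[y == 0L])) 1 else -1
  new_fitted_model("svm_linear",
                   list(svm = fit, flip = flip, cost = cost),
                   score_fun = function(par, Xn) {
                     par$flip * unname(drop(attr(
                       stats::predict(par$svm, as.matrix(Xn),
                                      decision.values = TRUE),
                       "decision.values")))
                   },
                   threshold = 0)
}

new_fitted_model <- function(family, parameters, score_fun, threshold) {
  structure(list(family = family, parameters = parameters,
                 score_fun = score_fun, threshold = threshold),
            class = "fitted_model")
}

#' Continuous scores / class labels from a fitted model
#'
#' Scores are oriented so that larger means more cancer-like;
#' [predict_labels()] thresholds them at the family's default cut
#' (0.5 on the 0/1 response scale for PLS-DA and RF vote fractions, 0 for
#' the SVM signed distance).
#'
#' @param model a `fitted_model`.
#' @param X feature matrix with the training feature count.
#' @return numeric scores, or character labels in
#'   \{`"cancer"`, `"control"`\}.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  model$score_fun(model$parameters, X)
}

#' @rdname predict_scores
#' @export
predict_labels <- function(model, X) {
  ifelse(predict_scores(model, X) >= model$threshold, "cancer", "control")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> family = %s\n", x$family))
  invisible(x)
}

#' Fit any family from a (tuned) model spec
#'
#' @param X feature matrix.
#' @param y labels.
#' @param spec a [model_spec()]; uses `spec$tuned` when present, otherwise
#'   the first grid candidate.
#' @param seed seed forwarded to stochastic families (RF).
#' @return a `fitted_model`.
#' @export
fit_model <- function(X, y, spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  par <- spec$tuned
  if (is.null(par)) {
    grid <- resolve_grid(spec, ncol(as.matrix(X)))
    par <- stats::setNames(list(grid[[1L]][1L]), names(grid))
  }
  switch(spec$family,
    plsda = fit_plsda(X, y, n_latent = par$n_latent),
    rf = fit_rf(X, y, mtry = par$mtry, n_trees = spec$n_trees, seed = seed),
    svm_linear = fit_svm_linear(X, y, cost = par$cost))
}

resolve_grid <- function(spec, p) {
  grid <- spec$grid
  if (spec$family == "rf" && is.null(grid$mtry)) grid$mtry <- default_mtry_grid(p)
  if (spec$family == "plsda") grid$n_latent <- grid$n_latent[grid$n_latent <= p]
  if (!length(grid[[1L]]))
    stop("resolve_grid: empty hyperparameter grid", call. = FALSE)
  grid
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Each synthetic sample is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0,1)`
#' and `x_nn` one of the `k` nearest minority-class neighbours of `x_i`
#' (Euclidean distance). Original rows are preserved unchanged and come
#' first in the output; only the minority class is augmented until the
#' target counts are reached. Applied to training data only — never before
#' splitting.
#'
#' @param X feature matrix.
#' @param y labels (0/1 or `"cancer"`/`"control"`).
#' @param k neighbour count (default 5; minority size must exceed `k`).
#' @param target named per-class target counts (`c(cancer = , control = )`);
#'   default balances both classes up to the majority count.
#' @param seed integer seed.
#' @return list with `X` (original rows then synthetic rows), `y` (0/1) and
#'   `synthetic` (logical marker per row).
#' @export
smote <- function(X, y, k = 5, target = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- coerce_labels(y)
  counts <- c(cancer = sum(y == 1L), control = sum(y == 0L))
  if (is.null(target)) {
    target <- c(cancer = max(counts), control = max(counts))
  }
  target <- target[c("cancer", "control")]
  need <- stats::setNames(pmax(0L, as.integer(target - counts)),
                          c("cancer", "control"))
  set.seed(as.integer(seed))
  Xs <- list()
  ys <- integer(0)
  for (cls in c("cancer", "control")) {
    n_extra <- need[[cls]]
    if (n_extra == 0L) next
    z <- if (cls == "cancer") 1L else 0L
    idx <- which(y == z)
    if (length(idx) <= k)
      stop("smote: class '", cls, "' has ", length(idx),
           " samples but k = ", k, " neighbours requested", call. = FALSE)
    Xm <- X[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(Xm))
    diag(d) <- Inf
    nn <- matrix(apply(d, 1L, function(r) order(r)[seq_len(k)]),
                 ncol = k, byrow = TRUE)
    seeds_i <- rep_len(seq_along(idx), n_extra)
    picks <- nn[cbind(seeds_i, sample.int(k, n_extra, replace = TRUE))]
    u <- stats::runif(n_extra)
    Xs[[cls]] <- Xm[seeds_i, , drop = FALSE] +
      u * (Xm[picks, , drop = FALSE] - Xm[seeds_i, , drop = FALSE])
    ys <- c(ys, rep(z, n_extra))
  }
  Xnew <- do.call(rbind, c(list(X), unname(Xs)))
  list(X = Xnew, y = c(y, ys),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, length(ys))))
}

#' Tune hyperparameters by grouped k-fold cross-validation
#'
#' Selects the grid candidate maximizing mean CV accuracy (spectrum-level).
#' When `groups` is given, folds are formed over groups (patients), so all
#' spectra of a patient share a fold and replicate leakage cannot inflate
#' CV accuracy. Ties break toward the simpler candidate (fewer latent
#' variables / smaller mtry / smaller cost — the earlier grid entry).
#'
#' @param X feature matrix.
#' @param y labels.
#' @param spec a [model_spec()].
#' @param folds number of folds (default 5; each fold must receive both
#'   classes).
#' @param seed integer seed (fold assignment and RF fits).
#' @param groups optional grouping vector (e.g. patient IDs), same length
#'   as `y`.
#' @return `spec` with `tuned` set; `attr(spec$tuned, "cv_accuracy")` holds
#'   the per-candidate mean CV accuracies.
#' @export
tune_cv <- function(X, y, spec, folds = 5, seed = 1L, groups = NULL) {
  stopifnot(inherits(spec, "model_spec"), folds >= 2)
  X <- as.matrix(X)
  y <- coerce_labels(y)
  grid <- resolve_grid(spec, ncol(X))
  par_name <- names(grid)[1L]
  cands <- grid[[1L]]
  if (is.null(groups)) groups <- seq_along(y)
  gu <- unique(groups)
  set.seed(as.integer(seed))
  fold_of_group <- stats::setNames(
    rep_len(seq_len(folds), length(gu))[sample.int(length(gu))], gu)
  fold <- fold_of_group[match(groups, gu)]
  acc <- numeric(length(cands))
  for (ci in seq_along(cands)) {
    sub <- spec
    sub$tuned <- stats::setNames(list(cands[ci]), par_name)
    correct <- 0L
    total <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) next
      m <- fit_model(X[tr, , drop = FALSE], y[tr], sub,
                     seed = as.integer(seed) + f)
      lab <- predict_labels(m, X[!tr, , drop = FALSE])
      correct <- correct + sum(lab == numeric_to_class(y[!tr]))
      total <- total + sum(!tr)
    }
    acc[ci] <- if (total) correct / total else NA_real_
  }
  if (all(is.na(acc)))
    stop("tune_cv: no fold contained both classes", call. = FALSE)
  best <- which.max(acc)  # first maximum: the simpler candidate wins ties
  spec$tuned <- stats::setNames(list(cands[best]), par_name)
  attr(spec$tuned, "cv_accuracy") <- stats::setNames(acc, cands)
  spec
}

# accept 0/1 numeric or cancer/control character labels
coerce_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (!all(y %in% c("cancer", "control")))
      stop("labels must be 'cancer'/'control' or 0/1", call. = FALSE)
    return(class_to_numeric(y))
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop("numeric labels must be 0/1", call. = FALSE)
  y
}
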