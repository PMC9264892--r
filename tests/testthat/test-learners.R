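make_toy <- function(n = 40, p = 6, sep = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), n / 2)
  X <- matrix(rnorm(n * p), n)
  X[, 1] <- X[, 1] + sep * y
  list(X = X, y = y)
}

test_that("PLS-DA reproduces a perfectly informative feature", {
  # single feature exactly equal to the response: one component suffices
  y <- rep(c(1L, 0L), 15)
  X <- cbind(2 * y - 5)
  m <- fit_plsda(X, y, n_latent = 1)
  sc <- predict_scores(m, X)
  expect_equal(pooled_roc(sc, y)$auc, 1.0)
  # scores reproduce y up to affine map
  expect_lt(max(abs(stats::lm(y ~ sc)$residuals)), 1e-8)
  # with noise features alongside, training AUC stays perfect
  set.seed(7)
  X2 <- cbind(y, matrix(rnorm(30 * 4, sd = 0.3), 30))
  m2 <- fit_plsda(X2, y, n_latent = 2)
  expect_equal(pooled_roc(predict_scores(m2, X2), y)$auc, 1.0)
})

test_that("PLS-DA latent scores are mutually orthogonal", {
  toy <- make_toy(n = 30, p = 8)
  m <- fit_plsda(toy$X, toy$y, n_latent = 5)
  Tm <- m$parameters$scores
  G <- crossprod(Tm)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("PLS-DA matches an independent PLS implementation", {
  toy <- make_toy(n = 24, p = 10, seed = 3)
  m <- fit_plsda(toy$X, toy$y, n_latent = 3)
  Xn <- toy$X
  colnames(Xn) <- paste0("f", 1:10)
  ref <- mixOmics::pls(Xn, toy$y, ncomp = 3, mode = "regression",
                       scale = FALSE)
  pred <- predict(ref, Xn)$predict[, 1, 3]
  expect_equal(unname(predict_scores(m, toy$X)), unname(pred),
               tolerance = 1e-8)
})

test_that("PLS-DA rejects degenerate requests", {
  toy <- make_toy(n = 10, p = 4)
  expect_error(fit_plsda(toy$X, rep(1L, 10), 1), "single-class")
  expect_error(fit_plsda(toy$X, toy$y, 9), "n_latent")
})

test_that("random forest finds a planted single-feature signal", {
  toy <- make_toy(n = 60, p = 8, sep = 3, seed = 5)
  m <- fit_rf(toy$X, toy$y, mtry = 3, n_trees = 200, seed = 9)
  expect_equal(which.max(m$parameters$importance), 1L)
  m2 <- fit_rf(toy$X, toy$y, mtry = 3, n_trees = 200, seed = 9)
  expect_identical(predict_scores(m, toy$X), predict_scores(m2, toy$X))
  expect_error(fit_rf(toy$X, toy$y, mtry = 20), "mtry")
})

test_that("a single unbagged tree separates a separable toy exactly", {
  toy <- make_toy(n = 30, p = 2, sep = 6, seed = 2)
  m <- fit_rf(toy$X, toy$y, mtry = 2, n_trees = 1, seed = 4,
              bootstrap = FALSE)
  expect_equal(predict_labels(m, toy$X),
               ifelse(toy$y == 1, "cancer", "control"))
})

test_that("linear SVM separates, orients and is stable to row duplication", {
  toy <- make_toy(n = 30, p = 2, sep = 5, seed = 8)
  m <- fit_svm_linear(toy$X, toy$y, cost = 100)
  expect_equal(predict_labels(m, toy$X),
               ifelse(toy$y == 1, "cancer", "control"))
  # orientation contract: flipping all labels negates the score
  mf <- fit_svm_linear(toy$X, 1L - toy$y, cost = 100)
  expect_equal(predict_scores(mf, toy$X), -predict_scores(m, toy$X),
               tolerance = 1e-6)
  # duplicating every row leaves the solution unchanged
  md <- fit_svm_linear(rbind(toy$X, toy$X), c(toy$y, toy$y), cost = 100)
  expect_equal(predict_scores(md, toy$X), predict_scores(m, toy$X),
               tolerance = 1e-6)
  expect_error(fit_svm_linear(cbind(c(1, NA), c(0, 1)), c(1L, 0L)),
               "non-finite")
})

test_that("all families orient scores toward cancer on training data", {
  toy <- make_toy(n = 40, p = 6, sep = 1.5, seed = 11)
  for (fam in c("plsda", "rf", "svm_linear")) {
    spec <- model_spec(fam)
    m <- fit_model(toy$X, toy$y, spec, seed = 3)
    sc <- predict_scores(m, toy$X)
    expect_gte(mean(sc[toy$y == 1]), mean(sc[toy$y == 0]))
  }
})

test_that("SMOTE balances classes by convex minority interpolation", {
  set.seed(21)
  X <- rbind(matrix(rnorm(35 * 4, mean = 2), 35),
             matrix(rnorm(100 * 4), 100))
  y <- c(rep("control", 35), rep("cancer", 100))
  out <- smote(X, y, k = 5, seed = 13)
  expect_equal(sum(out$y == 0L), 100L)
  expect_equal(sum(out$y == 1L), 100L)
  # originals preserved unchanged, first
  expect_identical(out$X[1:135, ], X)
  expect_equal(sum(out$synthetic), 65L)
  # each synthetic point lies in the minority bounding box
  syn <- out$X[out$synthetic, ]
  expect_true(all(t(syn) >= apply(X[1:35, ], 2, min) - 1e-12))
  expect_true(all(t(syn) <= apply(X[1:35, ], 2, max) + 1e-12))
})

test_that("SMOTE with k = 1 interpolates strictly on the segment", {
  a <- c(0, 0)
  b <- c(1, 2)
  X <- rbind(a, b, matrix(rnorm(20, mean = 5), 10))
  y <- c(1L, 1L, rep(0L, 10))
  out <- smote(X, y, k = 1, seed = 5)
  syn <- out$X[out$synthetic, , drop = FALSE]
  # every synthetic point is a + u (b - a): second coord = 2 x first
  expect_lt(max(abs(syn[, 2] - 2 * syn[, 1])), 1e-12)
  expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 1))
})

test_that("SMOTE no-ops on balanced data and validates k", {
  toy <- make_toy(n = 20, p = 3)
  out <- smote(toy$X, toy$y, seed = 2)
  expect_identical(out$X, toy$X)
  expect_identical(out$y, toy$y)
  y_small <- c(rep(1L, 3), rep(0L, 10))
  expect_error(smote(matrix(rnorm(26), 13), y_small, k = 5), "neighbour")
})

test_that("grouped CV tuning picks simpler candidates on ties", {
  toy <- make_toy(n = 40, p = 5, sep = 4, seed = 6)
  one <- model_spec("svm_linear", grid = list(cost = 1))
  expect_equal(tune_cv(toy$X, toy$y, one, seed = 1)$tuned$cost, 1)
  # strongly separable data: every cost ties at accuracy 1 -> smallest wins
  many <- model_spec("svm_linear", grid = list(cost = c(0.5, 5, 50)))
  tuned <- tune_cv(toy$X, toy$y, many, seed = 1)
  acc <- attr(tuned$tuned, "cv_accuracy")
  expect_equal(tuned$tuned$cost,
               c(0.5, 5, 50)[which.max(acc)])
  if (max(acc) == acc[1]) expect_equal(tuned$tuned$cost, 0.5)
})

test_that("tuning detects when two latent variables are required", {
  set.seed(33)
  n <- 120
  u <- rep(c(0L, 1L), n / 2)
  v <- rnorm(n)
  X <- cbind(u + 3 * v, v, matrix(rnorm(n * 3, sd = 0.5), n))
  tuned <- tune_cv(X, u, model_spec("plsda", grid = list(n_latent = 1:4)),
                   seed = 2)
  expect_gte(tuned$tuned$n_latent, 2L)
})

test_that("tuning with patient groups stays inside the grid", {
  ds <- tiny_cohort(n_cases = 5, n_controls = 5, seed = 2)
  prep <- serodisc:::quiet_bin(run_preprocess(ds, preprocess_config()))
  y <- ifelse(ds$meta$class == "cancer", 1L, 0L)
  tuned <- tune_cv(prep$matrix, y, model_spec("plsda"),
                   seed = 4, groups = ds$meta$patient_id)
  expect_true(tuned$tuned$n_latent %in% 1:15)
  expect_length(attr(tuned$tuned, "cv_accuracy"), 15L)
  expect_error(tune_cv(prep$matrix, y,
                       model_spec("plsda", grid = list(n_latent = integer(0)))),
               "empty")
})
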