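# brute-force pairwise AUC oracle: P(s_case > s_ctrl) + 0.5 P(tie)
auc_oracle <- function(scores, y) {
  sc <- scores[y == 1]
  sn <- scores[y == 0]
  tot <- 0
  for (a in sc) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sc) * length(sn))
}

test_that("patient splits stratify 70/30 and partition patients", {
  ds <- simulate_cohort(cohort_config(n_cases = 100, n_controls = 100,
                                      seed = 2),
                        axis = fp_axis(8))
  plan <- split_by_patient(ds, 0.7, seed = 5)
  expect_length(plan$train_patients, 140L)
  expect_length(plan$test_patients, 60L)
  cls <- serodisc:::class_per_patient(ds$meta)
  expect_equal(sum(cls[plan$train_patients] == "cancer"), 70L)
  expect_length(intersect(plan$train_patients, plan$test_patients), 0L)
  expect_setequal(c(plan$train_patients, plan$test_patients), names(cls))
  expect_identical(plan, split_by_patient(ds, 0.7, seed = 5))
  expect_false(identical(plan$train_patients,
                         split_by_patient(ds, 0.7, seed = 6)$train_patients))
})

test_that("splitting fails when a class has a single patient", {
  ds <- tiny_cohort(n_cases = 1, n_controls = 4)
  expect_error(split_by_patient(ds), "at least 2 patients")
})

test_that("consensus is the majority and is order-invariant", {
  v <- c(rep("cancer", 5), rep("control", 4))
  expect_equal(consensus(v), "cancer")
  expect_equal(consensus(sample(v)), "cancer")
  expect_equal(consensus(rep("cancer", 9)), "cancer")
  expect_equal(consensus(rep("control", 9)), "control")
  even <- c("cancer", "control")
  expect_error(consensus(even), "even vote")
  expect_equal(consensus(even, mean_score = 0.9), "cancer")
  expect_equal(consensus(even, mean_score = 0.1), "control")
})

test_that("metrics come from the confusion matrix with cancer positive", {
  truth <- c(rep("cancer", 4), rep("control", 4))
  expect_equal(classification_metrics(truth, truth),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  flip <- ifelse(truth == "cancer", "control", "cancer")
  expect_equal(classification_metrics(truth, flip),
               c(sensitivity = 0, specificity = 0, accuracy = 0))
  pred <- c("cancer", "cancer", "cancer", "control",  # TP=3 FN=1
            "cancer", "cancer", "control", "control") # FP=2 TN=2
  expect_equal(classification_metrics(truth, pred),
               c(sensitivity = 0.75, specificity = 0.5, accuracy = 0.625))
  expect_error(classification_metrics(rep("cancer", 3), rep("cancer", 3)),
               "single class")
})

test_that("ROC handles separation, ties and matches pROC", {
  expect_equal(pooled_roc(c(0.9, 0.8, 0.1, 0.2),
                          c(1, 1, 0, 0))$auc, 1.0)
  # one tied case/control pair among otherwise separated scores
  sc <- c(0.9, 0.5, 0.5, 0.1)
  y <- c(1, 1, 0, 0)
  expect_equal(pooled_roc(sc, y)$auc, 1 - 0.5 / 4)
  expect_equal(pooled_roc(sc, y)$auc, auc_oracle(sc, y))
  set.seed(19)
  s <- rnorm(40)
  yy <- rep(c(1, 0), 20)
  expect_equal(pooled_roc(s, yy)$auc,
               as.numeric(pROC::auc(pROC::roc(yy, s, quiet = TRUE))))
})

test_that("ROC AUC equals the pairwise oracle on random instances", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    r <- pooled_roc(s, y)
    expect_equal(r$auc, auc_oracle(s, y), tolerance = 1e-12)
    expect_true(all(diff(r$sensitivity) >= 0))        # along falling threshold
    expect_equal(r$sensitivity[c(1, length(r$sensitivity))], c(0, 1))
    expect_equal(r$specificity[c(1, length(r$specificity))], c(1, 0))
  }
})

test_that("a shuffled-label ROC is near chance", {
  set.seed(91)
  s <- rnorm(2000)
  y <- sample(rep(c(1, 0), 1000))
  expect_gt(pooled_roc(s, y)$auc, 0.45)
  expect_lt(pooled_roc(s, y)$auc, 0.55)
})

test_that("operating points respect the constraint region and nest", {
  perfect <- pooled_roc(c(1, 1, 0, 0), c(1, 1, 0, 0))
  ops <- operating_points(perfect, 0.6)
  expect_false(ops$empty)
  expect_equal(ops$points$sensitivity, c(1, 1, 1))
  expect_equal(ops$points$specificity, c(1, 1, 1))
  # random ROCs: the 0.45 region contains the 0.60 region
  set.seed(12)
  for (i in 1:10) {
    r <- pooled_roc(rnorm(60) + 0.8 * rep(c(1, 0), 30), rep(c(1, 0), 30))
    lo <- operating_points(r, 0.45)
    hi <- operating_points(r, 0.60)
    if (!hi$empty) {
      expect_false(lo$empty)
      expect_gte(lo$points$sensitivity[1], hi$points$sensitivity[1])
      expect_gte(lo$points$specificity[2], hi$points$specificity[2])
    }
  }
  # useless classifier: only boundary-ish points, possibly empty region
  flat <- pooled_roc(rep(0.5, 20), rep(c(1, 0), 10))
  expect_true(operating_points(flat, 0.6)$empty)
})

test_that("a perfectly informative band gives perfect consensus metrics", {
  ds <- tiny_cohort(n_cases = 5, n_controls = 5, effect_size = 30,
                    seed = 8, patient_sd = 0.001, bio_sd = 0.001,
                    tech_sd = 1e-4)
  s <- run_repeats(ds, model_spec("plsda"), n_repeats = 3, base_seed = 2)
  agg <- s$aggregate
  expect_equal(agg$mean[agg$metric %in%
                          c("sensitivity", "specificity", "accuracy")],
               rep(1, 3))
  expect_equal(agg$sd[agg$metric == "accuracy"], 0)
  expect_equal(s$roc$auc, 1.0)
  expect_equal(nrow(s$per_repeat), 3L)
})

test_that("repeat summaries are reproducible from the base seed", {
  ds <- tiny_cohort(n_cases = 4, n_controls = 4, seed = 14)
  a <- run_repeats(ds, model_spec("plsda"), n_repeats = 2, base_seed = 9)
  b <- run_repeats(ds, model_spec("plsda"), n_repeats = 2, base_seed = 9)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_identical(a$pooled, b$pooled)
})

test_that("the EMSC reference never depends on test rows", {
  ds <- tiny_cohort(n_cases = 4, n_controls = 4, seed = 5)
  plan <- split_by_patient(ds, 0.7, seed = 3)
  tr <- ds$meta$patient_id %in% plan$train_patients
  prep1 <- serodisc:::quiet_bin(
    run_preprocess(ds, preprocess_config(), train_rows = tr))
  tampered <- ds
  tampered$matrix[!tr, ] <- tampered$matrix[!tr, ] + 5
  prep2 <- serodisc:::quiet_bin(
    run_preprocess(tampered, preprocess_config(), train_rows = tr))
  expect_equal(prep1$matrix[tr, ], prep2$matrix[tr, ], tolerance = 1e-12)
})
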