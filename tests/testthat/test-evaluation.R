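test_that("confusion metrics follow the standard definitions", {
  rec <- data.frame(predicted = c(1, 1, 0, 0), truth = c(1, 1, 0, 0))
  expect_equal(unname(confusion_metrics(rec)), c(1, 1, 1),
               ignore_attr = TRUE)

  # 19 of 25 concussions and 30 of 33 non-injuries correct
  rec2 <- data.frame(
    predicted = c(rep(1, 19), rep(0, 6), rep(0, 30), rep(1, 3)),
    truth = c(rep(1, 25), rep(0, 33)))
  m <- confusion_metrics(rec2)
  expect_equal(round(m[["sensitivity"]], 3), 0.760)
  expect_equal(round(m[["specificity"]], 3), 0.909)
  expect_equal(m[["accuracy"]], 49 / 58)

  rec3 <- data.frame(predicted = rep(1, 10),
                     truth = rep(c(1, 0), each = 5))
  m3 <- confusion_metrics(rec3)
  expect_equal(m3[["sensitivity"]], 1)
  expect_equal(m3[["specificity"]], 0)
  expect_error(confusion_metrics(rec3[0, ]), "no prediction")
})

test_that("AUC equals the exhaustive pairwise-concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y))
  }
  expect_error(roc_auc(runif(4), rep(1, 4)), "both classes")

  # independent cross-check against pROC on a tied-score instance
  set.seed(8)
  y2 <- rep(c(1, 0), each = 12)
  s2 <- round(runif(24), 1)
  expect_equal(roc_auc(s2, y2)$auc,
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                              direction = "<"))))
})

test_that("the ROC curve starts at (0,0) and is monotone", {
  set.seed(3)
  s <- runif(30); y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  cv <- roc_auc(s, y)$curve
  expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
  expect_equal(c(max(cv$fpr), max(cv$tpr)), c(1, 1))
})

test_that("LOOCV yields one held-out record and training AUC per case", {
  ds <- tiny_dataset()
  cv <- loocv_run(ds, classifier_config("svm"),
                  selection_config("fscore"), seed = 8)
  n <- length(ds$cases)
  expect_equal(nrow(cv$records), n)
  expect_false(any(is.na(cv$records$p1)))
  expect_length(cv$train_auc, n)
  expect_length(Filter(Negate(is.null), cv$masks), n)
  expect_equal(cv$records$predicted, as.integer(cv$records$p1 >= 0.5))
  expect_named(cv$train_auc_summary,
               c("mean", "ci_lo", "ci_hi", "best", "worst"))
  # strong planted signal: the held-out accuracy is far above chance
  expect_gte(cv$metrics[["accuracy"]], 0.7)
})

test_that("per-fold selection and training never see the held-out case", {
  ds <- tiny_dataset()
  x <- dataset_features(ds); y <- dataset_labels(ds)
  cv1 <- loocv_run(list(x = x, y = y), classifier_config("svm"),
                   selection_config("fscore"), seed = 4)
  k <- 5L
  x2 <- x
  set.seed(1); x2[k, ] <- x2[k, ] + rnorm(ncol(x), 0, 0.5)
  cv2 <- loocv_run(list(x = x2, y = y), classifier_config("svm"),
                   selection_config("fscore"), seed = 4)
  # fold k's selection and trained model are untouched by the perturbation
  # (other folds legitimately change: case k sits in their training sets)
  expect_identical(cv1$masks[[k]]$indices, cv2$masks[[k]]$indices)
  expect_equal(cv1$train_auc[k], cv2$train_auc[k])
})

test_that(".632+ reproduces the hand-evaluated reference cases", {
  # no overfit: the estimate returns the training error
  expect_equal(dot632plus_error(0.2, 0.2, gamma = 0.5), 0.2)
  # the worked case err_train 0.1, err_oob 0.3, gamma 0.5
  expect_equal(dot632plus_error(0.1, 0.3, gamma = 0.5),
               0.1 + 0.2 * 0.632 / (1 - 0.368 * 0.5), tolerance = 1e-12)
  expect_equal(round(dot632plus_error(0.1, 0.3, gamma = 0.5), 4), 0.2549)
  # maximal overfit: weight goes fully onto the out-of-bag error
  expect_equal(dot632plus_error(0, 0.5, gamma = 0.5), 0.5)
  # gamma == err_train with err_oob above: R-clipping handles it
  expect_equal(dot632plus_error(0.3, 0.5, gamma = 0.3),
               dot632plus_error(0.3, 0.3, gamma = 0.3))
  expect_error(dot632plus_error(-0.1, 0.2, gamma = 0.5), "rates")

  # invariance to class relabeling (gamma is symmetric in p, q)
  y <- rbinom(30, 1, 0.4); y[1:2] <- c(0, 1)
  pr <- rbinom(30, 1, 0.5)
  a <- dot632plus_error(0.15, 0.3, labels = y, pred_train = pr)
  b <- dot632plus_error(0.15, 0.3, labels = 1 - y, pred_train = 1 - pr)
  expect_equal(a, b)
})

test_that("bootstrap evaluation keeps the trial contract and reproducibility", {
  ds <- tiny_dataset()
  cv <- bootstrap_run(ds, classifier_config("svm"),
                      selection_config("fscore"), n_boot = 8L, seed = 6)
  expect_equal(nrow(cv$trials), 8L)
  expect_true(all(cv$trials$accuracy >= 0 & cv$trials$accuracy <= 1))
  expect_true(cv$err632plus >= 0 && cv$err632plus <= 1)
  cv2 <- bootstrap_run(ds, classifier_config("svm"),
                       selection_config("fscore"), n_boot = 8L, seed = 6)
  expect_identical(cv$trials, cv2$trials)
  expect_error(bootstrap_run(ds, classifier_config("svm"), NULL,
                             n_boot = 1L), "n_boot")
})

test_that("a prevalence-only classifier scores the majority rate out of bag", {
  # constant feature: the univariate logistic collapses to the bag majority
  # imbalanced enough that the bag majority essentially never flips
  y <- rep(c(1L, 0L), c(15, 45))
  x <- matrix(1, length(y), 1)
  bs <- bootstrap_run(list(x = x, y = y), classifier_config("logistic"),
                      NULL, n_boot = 40L, seed = 2)
  expect_equal(mean(bs$trials$accuracy), 45 / 60, tolerance = 0.05)
})

test_that("bootstrap mean accuracy obeys the 1/sqrt(n) error law", {
  set.seed(10)
  y <- rep(c(1L, 0L), c(12, 16))
  x <- matrix(rnorm(28), 28, 1) + 0.8 * y
  b_small <- bootstrap_run(list(x = x, y = y),
                           classifier_config("logistic"), NULL,
                           n_boot = 30L, seed = 3)
  b_large <- bootstrap_run(list(x = x, y = y),
                           classifier_config("logistic"), NULL,
                           n_boot = 120L, seed = 4)
  se_small <- sd(b_small$trials$accuracy) / sqrt(30)
  se_large <- sd(b_large$trials$accuracy) / sqrt(120)
  # per-trial spread is stable, so quadrupling trials halves the SE
  expect_equal(se_small / se_large, 2, tolerance = 0.6)
})

test_that("randomized labels preserve class counts and report t-tests", {
  ds <- tiny_dataset()
  y <- dataset_labels(ds)
  pt <- randomized_label_test(ds, classifier_config("svm"),
                              selection_config("fscore"),
                              n_trials = 4L, seed = 15)
  expect_equal(nrow(pt$trials), 4L)
  expect_named(pt$p_values, c("accuracy", "sensitivity", "specificity"))
  # positive control: the unpermuted run is far above the permuted means
  cv <- loocv_run(ds, classifier_config("svm"), selection_config("fscore"),
                  seed = 15)
  expect_gt(cv$metrics[["accuracy"]], pt$means[["accuracy"]] + 0.1)
  # the permutation machinery preserves counts exactly
  set.seed(derive_seed(15, "perm", 1))
  expect_equal(sum(sample(y)), sum(y))
})
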