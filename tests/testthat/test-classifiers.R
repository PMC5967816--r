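test_that("deep training separates a strong synthetic signal", {
  ds <- tiny_dataset()
  x <- dataset_features(ds); y <- dataset_labels(ds)
  clf <- fit_classifier(x, y, classifier_config("deep"), seed = 3)
  p <- predict(clf, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean((p >= 0.5) == (y == 1)), 0.95)

  d <- attr(clf$fit, "diagnostics")
  tc <- training_config("desk")
  expect_gte(d$epochs_run, tc$min_epochs)
  expect_lte(d$epochs_run, tc$max_epochs)

  # predict agrees with a direct forward pass on the stored spec
  expect_equal(p, unname(forward(clf$fit, x)[, "p1"]))
})

test_that("deep training is deterministic for a fixed seed", {
  ds <- tiny_dataset()
  x <- dataset_features(ds); y <- dataset_labels(ds)
  c1 <- fit_classifier(x, y, classifier_config("deep"), seed = 9)
  c2 <- fit_classifier(x, y, classifier_config("deep"), seed = 9)
  expect_identical(attr(c1$fit, "diagnostics")$train_curve,
                   attr(c2$fit, "diagnostics")$train_curve)
  expect_identical(attr(c1$fit, "diagnostics")$val_curve,
                   attr(c2$fit, "diagnostics")$val_curve)
  expect_equal(predict(c1, x), predict(c2, x))
})

test_that("training_config enforces the epoch-range invariants", {
  expect_error(training_config(min_epochs = 10, probe_epochs = 20,
                               max_epochs = 50), "probe_epochs")
  expect_error(training_config(validation_fraction = 1.2), "validation")
  tc <- training_config("paper", reduced = FALSE)
  expect_equal(tc$learning_rate, 2e-8)
  expect_equal(training_config("paper", reduced = TRUE)$learning_rate, 1e-6)
  expect_equal(tc$batch_size, 5L)
  expect_equal(c(tc$min_epochs, tc$max_epochs), c(1000L, 5000L))
})

test_that("the linear SVM separates point clouds with monotone calibration", {
  set.seed(21)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- rep(c(0, 1), each = 20)
  clf <- fit_classifier(x, y, classifier_config("svm"), seed = 1)
  p <- predict(clf, x)
  expect_equal(mean((p >= 0.5) == (y == 1)), 1.0)
  expect_true(clf$fit$calibration$separated)

  # probabilities are monotone along the decision axis
  w_dir <- c(1, 1) / sqrt(2)
  line <- outer(seq(-2, 6, length.out = 15), w_dir)
  expect_true(all(diff(predict(clf, line)) > 0))
})

test_that("duplicating feature columns leaves linear-SVM predictions unchanged", {
  set.seed(31)
  x <- rbind(matrix(rnorm(60, 0, 1), 15), matrix(rnorm(60, 1.5, 1), 15))
  y <- rep(c(0, 1), each = 15)
  base <- fit_classifier(x, y, classifier_config("svm"), seed = 1)
  dup <- fit_classifier(cbind(x, x), y, classifier_config("svm"), seed = 1)
  xt <- rbind(matrix(rnorm(20, 0.8), 5), matrix(rnorm(20, 0.7), 5))
  expect_equal(predict(dup, cbind(xt, xt)), predict(base, xt),
               tolerance = 0.02)
})

test_that("RF honors the study-scale forest shapes and the trial contract", {
  ds <- tiny_dataset()
  x <- dataset_features(ds); y <- dataset_labels(ds)

  none <- fit_classifier(x, y, classifier_config("rf", n_trials = 1L),
                         seed = 2)
  expect_equal(none$fit$n_trees, 45L)
  expect_equal(none$fit$max_depth, 64L)

  mask <- select_features(x, y, selection_config("fscore"), seed = 2)
  fs <- fit_classifier(x, y, classifier_config("rf", n_trials = 1L),
                       mask = mask, seed = 2)
  expect_equal(fs$fit$n_trees, 75L)
  expect_equal(fs$fit$max_depth, 8L)
  expect_equal(rf_default_shape("rfvote"),
               c(n_trees = 75L, max_depth = 12L))

  # one trial: the trial distribution collapses onto the point prediction
  pt <- predict(none, x, type = "trials")
  expect_equal(dim(pt), c(1L, nrow(x)))
  expect_equal(drop(pt), predict(none, x))

  # per-(seed, trial) determinism
  again <- fit_classifier(x, y, classifier_config("rf", n_trials = 2L),
                          seed = 2)
  again2 <- fit_classifier(x, y, classifier_config("rf", n_trials = 2L),
                           seed = 2)
  expect_equal(predict(again, x, type = "trials"),
               predict(again2, x, type = "trials"))
})

test_that("RF on pure-noise features stays near chance on fresh cases", {
  set.seed(77)
  x <- matrix(rnorm(40 * 30), 40)
  y <- rep(c(0, 1), each = 20)
  clf <- fit_classifier(x, y, classifier_config("rf", n_trials = 3L),
                        seed = 5)
  x_new <- matrix(rnorm(200 * 30), 200)
  y_new <- rep(c(0, 1), each = 100)
  acc <- mean((predict(clf, x_new) >= 0.5) == (y_new == 1))
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("the classifier contract applies stored masks to full-length input", {
  ds <- tiny_dataset()
  x <- dataset_features(ds); y <- dataset_labels(ds)
  mask <- select_features(x, y, selection_config("fscore"), seed = 2)
  clf <- fit_classifier(x, y, classifier_config("svm"), mask = mask, seed = 2)
  expect_equal(clf$input_dim, length(mask$indices))
  # callers pass full-length rows; the mask is internal
  expect_silent(p <- predict(clf, x[1, ]))
  expect_true(p >= 0 && p <= 1)
  expect_error(predict(clf, x[, mask$indices]), "features")
})
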