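#' Confusion metrics from held-out prediction records
#'
#' Concussion is the positive class: accuracy = (TP+TN)/N, sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param records data.frame with columns `predicted` and `truth` (binary),
#'   e.g. the `records` of a [loocv_run()].
#' @return Named numeric: `accuracy`, `sensitivity`, `specificity`, plus the
#'   confusion counts as attribute `counts`.
#' @export
confusion_metrics <- function(records) {
  if (NROW(records) == 0L) stop("no prediction records")
  pred <- as.integer(records$predicted)
  truth <- as.integer(records$truth)
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  out <- c(accuracy = (tp + tn) / length(pred),
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  attr(out, "counts") <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  out
}

#' ROC curve and AUC
#'
#' AUC is the probability that a randomly drawn positive case outscores a
#' randomly drawn negative one, with ties counted one half (the
#' Mann-Whitney convention), computed from midranks. The ROC curve is
#' returned as the stepwise (FPR, TPR) points over all score thresholds.
#'
#' @param p1 probability (or any monotone score) per case.
#' @param truth binary truth per case.
#' @return List of class `roc_result`: `auc`, and `curve` (data.frame with
#'   `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(p1, truth) {
  y <- as.integer(truth)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to compute an ROC")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(p1)  # midranks handle ties
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(p1), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(p1[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p1[y == 0] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d curve points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

.as_features <- function(data) {
  if (inherits(data, "strain_dataset"))
    list(x = dataset_features(data), y = dataset_labels(data),
         ids = vapply(data$cases, function(cc) cc$case_id, character(1)))
  else
    list(x = as.matrix(data$x), y = as.integer(data$y),
         ids = if (!is.null(data$ids)) data$ids
               else sprintf("case%02d", seq_along(data$y)))
}

#' Leave-one-out cross-validation with per-fold feature selection
#'
#' For each of the `n` folds, feature selection and classifier training use
#' only the `n - 1` training cases — the held-out case is never seen by
#' either stage (the classical selection-bias guard) — and the held-out
#' case's concussion probability is recorded. A training-set AUC is computed
#' per fold from the fitted classifier's probabilities on its own training
#' cases, yielding `n` training AUCs summarized as mean, percentile 95% CI,
#' best and worst, alongside the single testing AUC over the `n` held-out
#' probabilities.
#'
#' @param data a [strain_dataset()], or a list with elements `x`
#'   (case-by-feature matrix) and `y` (binary labels).
#' @param classifier a [classifier_config()].
#' @param selection a [selection_config()] or `NULL`.
#' @param seed integer seed; fold `k` uses the child seed
#'   `derive_seed(seed, k)`.
#' @return Object of class `strain_loocv`: `records` (held-out prediction
#'   records), `metrics`, `auc_test`, `train_auc` (per fold) and its
#'   `train_auc_summary`, `masks` (per-fold selection masks), `failures`,
#'   and for RF the per-trial held-out probability matrix `trial_p`.
#' @export
loocv_run <- function(data, classifier, selection = NULL, seed = 1L) {
  d <- .as_features(data)
  x <- d$x; y <- d$y
  n <- length(y)
  if (n < 4L || length(unique(y)) < 2L)
    stop("LOOCV needs at least 4 cases and both classes")
  records <- data.frame(case_id = d$ids, fold_id = seq_len(n),
                        p1 = NA_real_, predicted = NA_integer_,
                        truth = y, stringsAsFactors = FALSE)
  train_auc <- rep(NA_real_, n)
  masks <- vector("list", n)
  failures <- character(0)
  trial_p <- NULL
  for (k in seq_len(n)) {
    sk <- derive_seed(seed, k)
    res <- tryCatch({
      mask <- select_features(x[-k, , drop = FALSE], y[-k], selection,
                              seed = sk, fold_id = k)
      clf <- fit_classifier(x[-k, , drop = FALSE], y[-k], classifier,
                            mask = mask, seed = sk)
      p_out <- predict(clf, x[k, , drop = FALSE])
      if (classifier$method == "rf") {
        pt <- predict(clf, x[k, , drop = FALSE], type = "trials")
        if (is.null(trial_p))
          trial_p <- matrix(NA_real_, nrow(pt), n)
        trial_p[, k] <- pt[, 1]
        # point decision: majority over the RF trials
        pred <- as.integer(mean(pt[, 1] >= 0.5) >= 0.5)
      } else {
        pred <- as.integer(p_out >= 0.5)
      }
      p_tr <- predict(clf, x[-k, , drop = FALSE])
      list(mask = mask, p1 = p_out, pred = pred,
           auc = roc_auc(p_tr, y[-k])$auc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("fold %d: %s", k, conditionMessage(res)))
      next
    }
    masks[[k]] <- res$mask
    records$p1[k] <- res$p1
    records$predicted[k] <- res$pred
    train_auc[k] <- res$auc
  }
  ok <- !is.na(records$predicted)
  if (!any(ok)) stop("every LOOCV fold failed; first failure: ", failures[1])
  out <- list(records = records,
              metrics = confusion_metrics(records[ok, ]),
              auc_test = roc_auc(records$p1[ok], records$truth[ok]),
              train_auc = train_auc,
              train_auc_summary = c(
                mean = mean(train_auc, na.rm = TRUE),
                ci_lo = unname(quantile(train_auc, 0.025, na.rm = TRUE)),
                ci_hi = unname(quantile(train_auc, 0.975, na.rm = TRUE)),
                best = max(train_auc, na.rm = TRUE),
                worst = min(train_auc, na.rm = TRUE)),
              masks = masks, failures = failures,
              trial_p = trial_p,
              classifier = classifier, selection = selection, seed = seed)
  class(out) <- "strain_loocv"
  out
}

#' @export
print.strain_loocv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("LOOCV (%s%s): accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$classifier$method,
              if (!is.null(x$selection) && x$selection$method != "none")
                paste0(" + ", x$selection$method) else "",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  cat(sprintf("  testing AUC %.3f | training AUC mean %.3f (95%% CI %.3f-%.3f, best %.3f, worst %.3f)\n",
              x$auc_test$auc, x$train_auc_summary["mean"],
              x$train_auc_summary["ci_lo"], x$train_auc_summary["ci_hi"],
              x$train_auc_summary["best"], x$train_auc_summary["worst"]))
  if (length(x$failures))
    cat("  failed folds:", length(x$failures), "\n")
  invisible(x)
}

#' The .632+ bootstrap error estimator
#'
#' Blends the apparent (training) error with the out-of-bag bootstrap error
#' using the relative-overfitting rate `R` against the no-information error
#' `gamma = p(1-q) + (1-p)q`, where `p` is the observed positive prevalence
#' and `q` the predicted-positive rate: after clamping
#' `err_oob <- min(err_oob, gamma)`,
#' `R = (err_oob - err_train) / (gamma - err_train)` (0 when the ratio is
#' undefined or the overfit is non-positive, clipped to `[0, 1]`),
#' `w = 0.632 / (1 - 0.368 R)`, and the estimate is
#' `(1 - w) err_train + w err_oob`.
#'
#' @param err_train apparent error rate in `[0, 1]`.
#' @param err_oob out-of-bag error rate in `[0, 1]`.
#' @param labels,pred_train binary truth and predictions on the training
#'   set, used to compute `gamma` (ignored when `gamma` is given).
#' @param gamma optional no-information error rate.
#' @return The .632+ error estimate.
#' @export
dot632plus_error <- function(err_train, err_oob, labels = NULL,
                             pred_train = NULL, gamma = NULL) {
  if (err_train < 0 || err_train > 1 || err_oob < 0 || err_oob > 1)
    stop("error rates must lie in [0, 1]")
  if (is.null(gamma)) {
    if (is.null(labels) || is.null(pred_train))
      stop("supply either gamma or labels + pred_train")
    p <- mean(as.integer(labels) == 1L)
    q <- mean(as.integer(pred_train) == 1L)
    gamma <- p * (1 - q) + (1 - p) * q
  }
  err_oob <- min(err_oob, gamma)  # overfitting clamp
  R <- if (err_oob > err_train && gamma > err_train)
    (err_oob - err_train) / (gamma - err_train) else 0
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  (1 - w) * err_train + w * err_oob
}

#' Out-of-bootstrap evaluation with the .632+ error
#'
#' Each trial draws `n` cases with replacement (redrawn, boundedly, if the
#' bag is single-class or the out-of-bag set empty), reruns feature
#' selection and fitting on the bag, and evaluates on the out-of-bag cases.
#' Alongside the per-trial metric distribution (mean and percentile 95% CI),
#' the .632+ error is computed from the full-data apparent error and the
#' mean out-of-bag error.
#'
#' @inheritParams loocv_run
#' @param n_boot number of bootstrap trials (default 100).
#' @param max_redraws bound on redraws per trial.
#' @return Object of class `strain_boot` with `trials` (per-trial metrics),
#'   `summary` (mean and 95% CI per metric), `err632plus`, `err_train`,
#'   `err_oob`, `gamma`.
#' @export
bootstrap_run <- function(data, classifier, selection = NULL,
                          n_boot = 100L, seed = 1L, max_redraws = 100L) {
  if (n_boot < 2L) stop("n_boot must be >= 2")
  d <- .as_features(data)
  x <- d$x; y <- d$y; n <- length(y)
  trials <- vector("list", n_boot)
  redraw_log <- 0L
  for (tr in seq_len(n_boot)) {
    set.seed(derive_seed(seed, "boot", tr))
    bag <- NULL
    for (rd in seq_len(max_redraws)) {
      cand <- sample(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), cand)
      if (length(unique(y[cand])) == 2L && length(oob) > 0L) {
        bag <- cand; break
      }
      redraw_log <- redraw_log + 1L
    }
    if (is.null(bag)) stop("could not draw a valid bootstrap bag")
    sk <- derive_seed(seed, "bootfit", tr)
    mask <- select_features(x[bag, , drop = FALSE], y[bag], selection,
                            seed = sk)
    clf <- fit_classifier(x[bag, , drop = FALSE], y[bag], classifier,
                          mask = mask, seed = sk)
    p_oob <- predict(clf, x[oob, , drop = FALSE])
    rec <- data.frame(predicted = as.integer(p_oob >= 0.5), truth = y[oob])
    cm <- confusion_metrics(rec)
    auc <- if (length(unique(y[oob])) == 2L)
      roc_auc(p_oob, y[oob])$auc else NA_real_
    trials[[tr]] <- c(cm, auc = auc, n_oob = length(oob))
  }
  tm <- do.call(rbind, trials)
  summ <- apply(tm[, c("accuracy", "sensitivity", "specificity", "auc")], 2,
                function(v) c(mean = mean(v, na.rm = TRUE),
                              ci_lo = unname(quantile(v, 0.025, na.rm = TRUE)),
                              ci_hi = unname(quantile(v, 0.975, na.rm = TRUE))))
  # .632+ from the full-data fit and the aggregate out-of-bag error
  sk <- derive_seed(seed, "fullfit")
  mask <- select_features(x, y, selection, seed = sk)
  clf <- fit_classifier(x, y, classifier, mask = mask, seed = sk)
  pred_train <- as.integer(predict(clf, x) >= 0.5)
  err_train <- mean(pred_train != y)
  err_oob <- mean(1 - tm[, "accuracy"])
  p <- mean(y == 1L); q <- mean(pred_train == 1L)
  gamma <- p * (1 - q) + (1 - p) * q
  out <- list(trials = as.data.frame(tm), summary = summ,
              err_train = err_train, err_oob = err_oob, gamma = gamma,
              err632plus = dot632plus_error(err_train, err_oob,
                                            gamma = gamma),
              redraws = redraw_log,
              classifier = classifier, selection = selection,
              n_boot = n_boot, seed = seed)
  class(out) <- "strain_boot"
  out
}

#' @export
print.strain_boot <- function(x, ...) {
  cat(sprintf("out-of-bootstrap (%s, %d trials): accuracy %.3f (%.3f-%.3f), .632+ error %.3f\n",
              x$classifier$method, x$n_boot,
              x$summary["mean", "accuracy"], x$summary["ci_lo", "accuracy"],
              x$summary["ci_hi", "accuracy"], x$err632plus))
  invisible(x)
}

#' Randomized-label validation
#'
#' Re-runs the full leave-one-out evaluation `n_trials` times with labels
#' randomly permuted (class counts preserved) before training, then tests
#' the per-trial mean accuracy, sensitivity and specificity against the 0.5
#' chance level by two-tailed one-sample t-tests. A classifier with genuine
#' predictive structure should drop to chance under permutation.
#'
#' @inheritParams loocv_run
#' @param n_trials number of permutation trials (default 50).
#' @return Object of class `strain_permtest`: `trials` (per-trial metrics),
#'   `means`, `p_values` (t-test vs 0.5 per metric).
#' @export
randomized_label_test <- function(data, classifier, selection = NULL,
                                  n_trials = 50L, seed = 1L) {
  if (n_trials < 2L) stop("n_trials must be >= 2")
  d <- .as_features(data)
  x <- d$x; y <- d$y
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(derive_seed(seed, "perm", tr))
    y_perm <- sample(y)  # preserves class counts exactly
    cv <- loocv_run(list(x = x, y = y_perm), classifier, selection,
                    seed = derive_seed(seed, "permcv", tr))
    trials[[tr]] <- cv$metrics
  }
  tm <- as.data.frame(do.call(rbind, trials))
  pv <- vapply(c("accuracy", "sensitivity", "specificity"), function(mname) {
    v <- tm[[mname]]
    if (sd(v, na.rm = TRUE) == 0) return(as.numeric(all(v == 0.5)))
    t.test(v, mu = 0.5)$p.value
  }, numeric(1))
  out <- list(trials = tm, means = colMeans(tm, na.rm = TRUE),
              p_values = pv, n_trials = n_trials,
              classifier = classifier, selection = selection, seed = seed)
  class(out) <- "strain_permtest"
  out
}

#' @export
print.strain_permtest <- function(x, ...) {
  cat(sprintf("randomized-label test (%s, %d trials): mean accuracy %.3f (t-test vs 0.5: p = %.3g)\n",
              x$classifier$method, x$n_trials, x$means["accuracy"],
              x$p_values["accuracy"]))
  invisible(x)
}
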