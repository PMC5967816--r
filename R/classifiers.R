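#' Classifier configuration
#'
#' One configuration object covers the three feature-based classifiers. RF
#' forest shapes default to the empirically tuned study-scale values per
#' selection method: (trees, depth) = (45, 64) without selection, (75, 8)
#' with F-score selection, (75, 12) with RF-voting selection.
#'
#' @param method `"deep"`, `"svm"`, `"rf"`, or `"logistic"` (univariate, for
#'   scalar-metric baselines).
#' @param scale `"desk"` or `"paper"`; sizes the deep network and the RF
#'   trial count.
#' @param training a [training_config()] for `"deep"` (built from `scale`
#'   when omitted).
#' @param widths deep network layer widths (derived from the input size and
#'   `scale` via [pyramid_widths()] when omitted).
#' @param cost linear-SVM cost parameter C (default 1).
#' @param n_trees,max_depth RF forest shape overrides.
#' @param n_trials number of independently seeded RF repetitions per fit
#'   (study scale 100; desk default 5).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(method = c("deep", "svm", "rf", "logistic"),
                              scale = c("desk", "paper"),
                              training = NULL, widths = NULL,
                              cost = 1,
                              n_trees = NULL, max_depth = NULL,
                              n_trials = NULL) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (is.null(n_trials)) n_trials <- if (scale == "paper") 100L else 5L
  structure(list(method = method, scale = scale, training = training,
                 widths = widths, cost = cost,
                 n_trees = n_trees, max_depth = max_depth,
                 n_trials = as.integer(n_trials)),
            class = "classifier_config")
}

#' @rdname classifier_config
#' @param selection_method the selection method in force (`"none"`,
#'   `"fscore"`, `"rfvote"`); picks the study-scale RF forest shape.
#' @export
rf_default_shape <- function(selection_method = "none") {
  switch(selection_method,
         none = c(n_trees = 45L, max_depth = 64L),
         fscore = c(n_trees = 75L, max_depth = 8L),
         rfvote = c(n_trees = 75L, max_depth = 12L),
         c(n_trees = 45L, max_depth = 64L))
}

.apply_mask <- function(x, mask) {
  if (is.null(mask)) return(x)
  x[, mask$indices, drop = FALSE]
}

# ranger requires named covariates; name columns by feature position
.named_matrix <- function(x) {
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  x
}

#' Fit a concussion classifier
#'
#' The single fitting entry point behind which the three feature-based
#' classifiers (and the univariate logistic baseline) live. Callers always
#' pass full-length feature rows; when a selection mask is supplied it is
#' stored in the fitted object and applied internally both here and in
#' `predict`.
#'
#' @param features case-by-voxel matrix (full feature space).
#' @param labels binary labels (1 = concussion).
#' @param config a [classifier_config()].
#' @param mask optional `selection_mask` from [select_features()].
#' @param seed integer seed controlling every random element of the fit.
#' @return An object of class `c("<method>_strain_clf", "strain_clf")` with
#'   `predict`, `print` and `summary` methods.
#' @export
fit_classifier <- function(features, labels, config = classifier_config(),
                           mask = NULL, seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  x <- .apply_mask(as.matrix(features), mask)
  fit <- switch(config$method,
    deep = .fit_deep(x, y, config, seed),
    svm = .fit_svm(x, y, config, seed),
    rf = .fit_rf(x, y, config, mask, seed),
    logistic = .fit_logit(x, y, config))
  structure(list(method = config$method, config = config, fit = fit,
                 mask = mask, input_dim = ncol(x),
                 full_dim = ncol(as.matrix(features)), seed = seed),
            class = c(paste0(config$method, "_strain_clf"), "strain_clf"))
}

.fit_deep <- function(x, y, config, seed) {
  tc <- config$training
  if (is.null(tc))
    tc <- training_config(scale = config$scale, reduced = ncol(x) <= 1000,
                          seed = seed)
  else tc$seed <- seed
  widths <- config$widths
  if (is.null(widths))
    widths <- pyramid_widths(ncol(x), scale = config$scale,
                             reduced = ncol(x) <= 1000)
  spec <- network_spec(ncol(x), widths)
  train_deep(x, y, spec, tc)
}

.fit_svm <- function(x, y, config, seed) {
  if (nrow(x) != length(y)) stop("feature/label size mismatch")
  sv <- e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)),
                   kernel = "linear", cost = config$cost, scale = FALSE)
  pr <- predict(sv, x, decision.values = TRUE)
  dvm <- attr(pr, "decision.values")
  # orient the decision value so that larger means concussion (class "1")
  sgn <- if (identical(colnames(dvm)[1], "0/1")) -1 else 1
  dv <- sgn * drop(dvm)
  calib <- fit_univariate_logistic(dv, y, metric_name = "svm_decision")
  list(svm = sv, sign = sgn, calibration = calib,
       train_accuracy = mean((pr == "1") == (y == 1L)))
}

.fit_rf <- function(x, y, config, mask, seed) {
  n_trees <- config$n_trees
  max_depth <- config$max_depth
  sel <- if (is.null(mask)) "none" else mask$method
  shape <- rf_default_shape(sel)
  if (is.null(n_trees)) n_trees <- shape[["n_trees"]]
  if (is.null(max_depth)) max_depth <- shape[["max_depth"]]
  if (n_trees < 1L) stop("n_trees must be >= 1")
  yf <- factor(y, levels = c(0L, 1L))
  x <- .named_matrix(x)
  trials <- lapply(seq_len(config$n_trials), function(tr) {
    ranger::ranger(x = x, y = yf, num.trees = n_trees,
                   max.depth = max_depth, probability = TRUE,
                   seed = derive_seed(seed, "rftrial", tr),
                   num.threads = 1L, verbose = FALSE)
  })
  list(trials = trials, n_trees = n_trees, max_depth = max_depth)
}

.fit_logit <- function(x, y, config) {
  if (ncol(x) != 1L)
    stop("the univariate logistic classifier takes exactly one feature")
  fit_univariate_logistic(drop(x), y)
}

#' Predict concussion probability
#'
#' @param object a fitted [fit_classifier()] object.
#' @param newdata case-by-voxel matrix in the *full* feature space (any
#'   stored selection mask is applied internally), or a single full-length
#'   vector.
#' @param type `"prob"` for the mean concussion probability `p1`;
#'   `"trials"` (RF only) for the per-trial probability matrix
#'   (trials x cases).
#' @param ... unused.
#' @return Numeric vector of `p1` in `[0, 1]` (or the per-trial matrix); the
#'   classification rule is `p1 >= 0.5`.
#' @export
predict.strain_clf <- function(object, newdata, type = c("prob", "trials"),
                               ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$full_dim)
    stop("newdata has ", ncol(newdata), " features; the classifier was ",
         "fitted on ", object$full_dim)
  x <- .apply_mask(as.matrix(newdata), object$mask)
  if (type == "trials") {
    if (object$method != "rf") stop("type = 'trials' applies to RF only")
    x <- .named_matrix(x)
    p_list <- lapply(object$fit$trials, function(f)
      predict(f, data = x, num.threads = 1L,
              verbose = FALSE)$predictions[, "1"])
    return(matrix(unlist(p_list), nrow = length(p_list), ncol = nrow(x),
                  byrow = TRUE))
  }
  switch(object$method,
    deep = unname(forward(object$fit, x)[, "p1"]),
    svm = {
      dv <- object$fit$sign *
        drop(attr(predict(object$fit$svm, x, decision.values = TRUE),
                  "decision.values"))
      predict(object$fit$calibration, dv)
    },
    rf = {
      pt <- predict.strain_clf(object, newdata, type = "trials")
      colMeans(pt)
    },
    logistic = predict(object$fit, drop(x)))
}

#' @export
print.strain_clf <- function(x, ...) {
  cat("strain classifier:", x$method,
      "| input features:", x$input_dim,
      if (!is.null(x$mask)) paste0("(selected by ", x$mask$method, ")")
      else "(no selection)", "\n")
  invisible(x)
}

#' @export
summary.strain_clf <- function(object, ...) {
  print(object)
  if (object$method == "deep") {
    d <- attr(object$fit, "diagnostics")
    cat(sprintf("  widths: %s | epochs: %d (best %d) | restarts: %d | best val error: %.4f\n",
                paste(object$fit$layer_widths, collapse = "-"),
                d$epochs_run, d$best_epoch, d$restarts_used,
                d$best_val_error))
  }
  if (object$method == "rf")
    cat(sprintf("  %d trials of %d trees, depth %d\n",
                length(object$fit$trials), object$fit$n_trees,
                object$fit$max_depth))
  invisible(object)
}
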