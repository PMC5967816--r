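#' Assemble an evaluation report
#'
#' Collects the results of the evaluation modes (LOOCV, out-of-bootstrap,
#' randomized-label validation) for one or more classifiers into a single
#' report object, with per-mode metric tables mirroring the usual summary
#' layout (accuracy / sensitivity / specificity rows, one column per
#' classifier; testing AUC and the mean/CI/best/worst training AUC for
#' LOOCV; .632+ error for the bootstrap), plus ROC coordinates and any
#' selection probability maps.
#'
#' @param loocv named list of [loocv_run()] results (one per classifier).
#' @param boot named list of [bootstrap_run()] results.
#' @param permtest named list of [randomized_label_test()] results.
#' @param maps named list of [selection_probability_map()] objects.
#' @return Object of class `strain_report` with `tables` (data.frames per
#'   mode), `roc` (testing-curve coordinates plus best/worst training-fold
#'   ids), and the raw inputs.
#' @export
assemble_report <- function(loocv = list(), boot = list(), permtest = list(),
                            maps = list()) {
  if (length(loocv) + length(boot) + length(permtest) == 0L)
    stop("nothing to report: supply at least one evaluated classifier")
  tables <- list()
  if (length(loocv)) {
    tables$loocv <- data.frame(
      classifier = names(loocv),
      accuracy = vapply(loocv, function(r) r$metrics[["accuracy"]], 0),
      sensitivity = vapply(loocv, function(r) r$metrics[["sensitivity"]], 0),
      specificity = vapply(loocv, function(r) r$metrics[["specificity"]], 0),
      auc_testing = vapply(loocv, function(r) r$auc_test$auc, 0),
      auc_training_mean = vapply(loocv, function(r)
        r$train_auc_summary[["mean"]], 0),
      auc_training_ci_lo = vapply(loocv, function(r)
        r$train_auc_summary[["ci_lo"]], 0),
      auc_training_ci_hi = vapply(loocv, function(r)
        r$train_auc_summary[["ci_hi"]], 0),
      auc_training_best = vapply(loocv, function(r)
        r$train_auc_summary[["best"]], 0),
      auc_training_worst = vapply(loocv, function(r)
        r$train_auc_summary[["worst"]], 0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(boot)) {
    tables$bootstrap <- data.frame(
      classifier = names(boot),
      accuracy = vapply(boot, function(r) r$summary["mean", "accuracy"], 0),
      sensitivity = vapply(boot, function(r)
        r$summary["mean", "sensitivity"], 0),
      specificity = vapply(boot, function(r)
        r$summary["mean", "specificity"], 0),
      auc = vapply(boot, function(r) r$summary["mean", "auc"], 0),
      err632plus = vapply(boot, function(r) r$err632plus, 0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(permtest)) {
    tables$permtest <- data.frame(
      classifier = names(permtest),
      mean_accuracy = vapply(permtest, function(r) r$means[["accuracy"]], 0),
      mean_sensitivity = vapply(permtest, function(r)
        r$means[["sensitivity"]], 0),
      mean_specificity = vapply(permtest, function(r)
        r$means[["specificity"]], 0),
      p_accuracy = vapply(permtest, function(r) r$p_values[["accuracy"]], 0),
      p_sensitivity = vapply(permtest, function(r)
        r$p_values[["sensitivity"]], 0),
      p_specificity = vapply(permtest, function(r)
        r$p_values[["specificity"]], 0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  roc <- lapply(loocv, function(r) {
    list(testing = r$auc_test$curve,
         best_fold = which.max(r$train_auc),
         worst_fold = which.min(r$train_auc))
  })
  structure(list(tables = tables, roc = roc, loocv = loocv, boot = boot,
                 permtest = permtest, maps = maps),
            class = "strain_report")
}

#' @export
print.strain_report <- function(x, ...) {
  for (mode in names(x$tables)) {
    cat("==", mode, "==\n")
    print(x$tables[[mode]], digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per evaluation mode, ROC coordinates as CSV, a JSON summary (all
#' floating point serialized at fixed precision so a fixed-seed rerun is
#' byte-identical), and optional ROC overlay plots.
#'
#' @param report a [assemble_report()] result.
#' @param dir output directory.
#' @param plots write PNG ROC plots too?
#' @param digits decimal places used in the JSON summary.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, plots = FALSE, digits = 6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mode in names(report$tables))
    write.csv(report$tables[[mode]],
              file.path(dir, paste0(mode, "_metrics.csv")),
              row.names = FALSE)
  for (nm in names(report$roc))
    write.csv(report$roc[[nm]]$testing,
              file.path(dir, paste0("roc_testing_", nm, ".csv")),
              row.names = FALSE)
  summ <- lapply(report$tables, function(tb) {
    tb[] <- lapply(tb, function(col)
      if (is.numeric(col)) round(col, digits) else col)
    tb
  })
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (plots && length(report$roc)) {
    png(file.path(dir, "roc_testing.png"), width = 700, height = 700)
    plot(report, which = "testing")
    dev.off()
  }
  invisible(dir)
}

#' Plot testing ROC curves of a report
#'
#' @param x a `strain_report`.
#' @param which `"testing"` (all classifiers overlaid).
#' @param ... passed to [graphics::plot()].
#' @export
plot.strain_report <- function(x, which = "testing", ...) {
  if (length(x$roc) == 0L) stop("report contains no ROC curves")
  cols <- seq_along(x$roc)
  plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
       ylab = "True positive rate", main = "Held-out ROC", ...)
  abline(0, 1, col = "grey70", lty = 2)
  for (i in cols) {
    cv <- x$roc[[i]]$testing
    lines(c(cv$fpr, 1), c(cv$tpr, 1), col = i, lwd = 2, type = "s")
  }
  legend("bottomright", legend = names(x$roc), col = cols, lwd = 2,
         bty = "n")
  invisible(x)
}

#' Plot deep-network training diagnostics
#'
#' Training loss and internal-validation error per epoch for a fitted deep
#' classifier.
#'
#' @param clf a fitted deep [fit_classifier()] object.
#' @export
plot_training_curves <- function(clf) {
  if (!inherits(clf, "deep_strain_clf")) stop("not a deep classifier")
  d <- attr(clf$fit, "diagnostics")
  ep <- seq_along(d$train_curve)
  plot(ep, d$train_curve, type = "l", lwd = 2, xlab = "epoch",
       ylab = "cross-entropy", ylim = range(c(d$train_curve, d$val_curve)))
  lines(ep, d$val_curve, col = 2, lwd = 2)
  abline(v = d$best_epoch, lty = 3)
  legend("topright", c("training", "validation"), col = c(1, 2), lwd = 2,
         bty = "n")
  invisible(clf)
}
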