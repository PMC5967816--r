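#' Critical angular velocities for BrIC
#'
#' Defaults are the WHIM-specific critical values: 30.4, 35.6 and 23.5 rad/s
#' about the x (posterior-anterior), y (right-left) and z
#' (inferior-superior) axes.
#'
#' @param wxc,wyc,wzc positive critical angular velocities, rad/s.
#' @return A list of class `critical_velocities`.
#' @export
critical_velocities <- function(wxc = 30.4, wyc = 35.6, wzc = 23.5) {
  if (any(c(wxc, wyc, wzc) <= 0))
    stop("critical velocities must be positive")
  structure(list(wxc = wxc, wyc = wyc, wzc = wzc),
            class = "critical_velocities")
}

#' Brain Injury Criterion (BrIC)
#'
#' Root-sum-square of the per-axis peak angular velocity magnitudes, each
#' normalized by its model-specific critical value:
#' `sqrt((wx/wxc)^2 + (wy/wyc)^2 + (wz/wzc)^2)`. The input 3-vector is
#' interpreted as per-axis peak magnitudes.
#'
#' @param peak_ang_vel numeric length-3, rad/s, all `>= 0`.
#' @param crit a [critical_velocities()].
#' @return Non-negative dimensionless score.
#' @export
compute_bric <- function(peak_ang_vel, crit = critical_velocities()) {
  w <- as.numeric(peak_ang_vel)
  if (length(w) != 3L) stop("peak_ang_vel must have length 3")
  if (any(w < 0)) stop("peak_ang_vel components must be non-negative")
  sqrt((w[1] / crit$wxc)^2 + (w[2] / crit$wyc)^2 + (w[3] / crit$wzc)^2)
}

#' Cumulative strain damage measure (CSDM)
#'
#' Volume fraction (voxel-count weighted) of a region whose peak maximum
#' principal strain strictly exceeds the threshold. The strict inequality is
#' an arbitrary-but-fixed convention; it only matters for synthetic volumes
#' with constant values at the boundary.
#'
#' @param case a [strain_case()].
#' @param region_mask logical 3D array on the case's grid.
#' @param threshold dimensionless strain threshold (default 0.2).
#' @return Fraction in `[0, 1]`.
#' @export
compute_csdm <- function(case, region_mask, threshold = 0.2) {
  if (!identical(dim(region_mask), dim(case$mps)))
    stop("region_mask dimensions do not match the case volumes")
  idx <- which(region_mask != 0)
  if (length(idx) == 0L) stop("region_mask is empty")
  mean(case$mps[idx] > threshold)
}

#' Peak fiber strain over an ROI
#'
#' @param case a [strain_case()].
#' @param grid the case's [volume_grid()].
#' @param roi_label integer ROI code (default 1, the corpus callosum).
#' @return Maximum fiber strain over the ROI's voxels.
#' @export
compute_peak_roi <- function(case, grid, roi_label = 1L) {
  idx <- which(grid$roi_labels == roi_label)
  if (length(idx) == 0L)
    stop("ROI label ", roi_label, " has no voxels on this grid")
  max(case$fiber_strain[idx])
}

#' Per-case scalar injury metric table
#'
#' Computes BrIC, CSDM-WB (whole brain), CSDM-CC (corpus callosum) and
#' Peak-CC for every case of a dataset.
#'
#' @param dataset a [strain_dataset()].
#' @param crit BrIC [critical_velocities()].
#' @param csdm_threshold CSDM strain threshold (default 0.2).
#' @return `data.frame` with columns `case_id, BrIC, CSDM_WB, CSDM_CC,
#'   Peak_CC, label`.
#' @export
metric_table <- function(dataset, crit = critical_velocities(),
                         csdm_threshold = 0.2) {
  g <- dataset$grid
  cc_mask <- g$roi_labels == 1L
  rows <- lapply(dataset$cases, function(cc) {
    data.frame(case_id = cc$case_id,
               BrIC = compute_bric(cc$peak_ang_vel, crit),
               CSDM_WB = compute_csdm(cc, g$brain_mask, csdm_threshold),
               CSDM_CC = compute_csdm(cc, cc_mask, csdm_threshold),
               Peak_CC = compute_peak_roi(cc, g, 1L),
               label = cc$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# penalized (ridge on the slope) univariate logistic fit by Newton/IRLS,
# on standardized x; used only when the classes are linearly separated
.ridge_logistic <- function(x, y, lambda, max_iter = 100, tol = 1e-10) {
  beta <- c(qlogis(max(min(mean(y), 1 - 1e-3), 1e-3)), 0)
  X <- cbind(1, x)
  pen <- diag(c(0, lambda))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(X, y - p)) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Univariate logistic regression for a scalar injury metric
#'
#' Maximum-likelihood fit of `logit P(concussion) = a + b * metric` via
#' [stats::glm()]. Complete separation (a threshold on the metric perfectly
#' splits the classes — easy to detect exactly in one dimension) is flagged
#' and handled by refitting with a small ridge penalty on the slope instead
#' of returning divergent coefficients; a zero-variance metric yields slope
#' 0 and an intercept-only model (predicted probability = class prevalence).
#'
#' @param metric_values numeric per training case.
#' @param labels binary per case (1 = concussion).
#' @param metric_name stored for reporting.
#' @param ridge penalty used in the separated fallback.
#' @return Object of class `logistic_model` with fields `intercept`, `slope`,
#'   `metric_name`, `separated`.
#' @export
fit_univariate_logistic <- function(metric_values, labels,
                                    metric_name = "metric", ridge = 1e-2) {
  x <- as.numeric(metric_values)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (min(table(y)) < 2L) stop("need at least 2 cases per class")
  if (sd(x) == 0) {
    m <- list(intercept = qlogis(mean(y)), slope = 0,
              metric_name = metric_name, separated = FALSE,
              center = 0, scale = 1)
    class(m) <- "logistic_model"
    return(m)
  }
  separated <- max(x[y == 0]) < min(x[y == 1]) ||
    max(x[y == 1]) < min(x[y == 0])
  ctr <- mean(x); scl <- sd(x)
  xs <- (x - ctr) / scl
  if (!separated) {
    fit <- suppressWarnings(glm(y ~ xs, family = binomial()))
    beta <- coef(fit)
  } else {
    beta <- .ridge_logistic(xs, y, lambda = ridge)
  }
  m <- list(intercept = unname(beta[1] - beta[2] * ctr / scl),
            slope = unname(beta[2] / scl),
            metric_name = metric_name, separated = separated,
            center = ctr, scale = scl)
  class(m) <- "logistic_model"
  m
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("univariate logistic model for %s: logit(p) = %.4g + %.4g * x%s\n",
              x$metric_name, x$intercept, x$slope,
              if (x$separated) "  [complete separation; ridge fit]" else ""))
  invisible(x)
}

#' Predict concussion probability from a fitted univariate logistic model
#'
#' @param object a `logistic_model` from [fit_univariate_logistic()].
#' @param newdata numeric metric values.
#' @param ... unused.
#' @return Probabilities in `(0, 1)`; the classification rule is
#'   `probability >= 0.5`.
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  if (is.null(object$intercept)) stop("model is not fitted")
  plogis(object$intercept + object$slope * as.numeric(newdata))
}

#' @rdname predict.logistic_model
#' @param model a `logistic_model`.
#' @param metric_value numeric metric value(s).
#' @export
predict_logistic <- function(model, metric_value) {
  predict.logistic_model(model, metric_value)
}
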