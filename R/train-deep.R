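#' Deep network training configuration
#'
#' Study-scale defaults follow the reference training protocol: ADAM with
#' `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`; learning rate `2e-8` for
#' the full-input network or `1e-6` for the reduced network; batch size 5
#' with short final batches topped up by random resampling; an internal
#' stratified 10% validation split; a 300-epoch probe after which a run
#' whose validation error has not decreased is restarted as a failed
#' initialization; and an admissible stopping range of 1000 to 5000 epochs.
#' Desk-scale presets retune the learning rate and the epoch range for the
#' much smaller synthetic networks (the study-scale values are tied to the
#' 64k-voxel input scale); all other semantics are identical.
#'
#' @param scale `"desk"` or `"paper"`.
#' @param reduced network sized for a selected feature set? (chooses the
#'   paper learning rate 1e-6 vs 2e-8).
#' @param learning_rate,batch_size,max_epochs,min_epochs,probe_epochs,patience
#'   overrides of the preset.
#' @param validation_fraction internal validation split (default 0.10).
#' @param adam_beta1,adam_beta2,adam_eps ADAM moment parameters.
#' @param max_restarts permitted reinitializations after failed probes.
#' @param momentum accepted for config-file compatibility and ignored: the
#'   ADAM betas fully specify the optimizer.
#' @param seed integer seed.
#' @return A list of class `training_config`.
#' @export
training_config <- function(scale = c("desk", "paper"), reduced = TRUE,
                            learning_rate = NULL, batch_size = 5L,
                            max_epochs = NULL, min_epochs = NULL,
                            probe_epochs = NULL, patience = NULL,
                            validation_fraction = 0.10,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-8, max_restarts = 5L,
                            momentum = NULL, seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "paper") {
    if (is.null(learning_rate)) learning_rate <- if (reduced) 1e-6 else 2e-8
    if (is.null(max_epochs)) max_epochs <- 5000L
    if (is.null(min_epochs)) min_epochs <- 1000L
    if (is.null(probe_epochs)) probe_epochs <- 300L
    if (is.null(patience)) patience <- 200L
  } else {
    if (is.null(learning_rate)) learning_rate <- 3e-3
    if (is.null(max_epochs)) max_epochs <- 60L
    if (is.null(min_epochs)) min_epochs <- 25L
    if (is.null(probe_epochs)) probe_epochs <- 8L
    if (is.null(patience)) patience <- 12L
  }
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)")
  if (!(probe_epochs < min_epochs && min_epochs <= max_epochs))
    stop("need probe_epochs < min_epochs <= max_epochs")
  structure(list(scale = scale, reduced = reduced,
                 learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 min_epochs = as.integer(min_epochs),
                 probe_epochs = as.integer(probe_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed)),
            class = "training_config")
}

# stratified validation split: at least one case per class in validation
.validation_split <- function(y, fraction) {
  n <- length(y)
  val <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    k <- max(1L, round(fraction * length(idx)))
    val <- c(val, sample(idx, k))
  }
  sort(val)
}

#' Train the deep classifier network
#'
#' Splits off a stratified internal validation set, minimizes softmax
#' cross-entropy by ADAM in batches of `batch_size` (short final batches
#' topped up by random resampling), monitors the validation error, restarts
#' on a failed probe, stops within the admissible epoch range once the
#' validation error has not improved for `patience` epochs, and retains the
#' parameters with the best validation error.
#'
#' @param features case-by-feature training matrix.
#' @param labels binary training labels.
#' @param spec a [network_spec()] template (widths/activations; weights are
#'   initialized internally, once per permitted restart).
#' @param config a [training_config()].
#' @return A fitted `network_spec` with attached `bn` statistics and a
#'   `diagnostics` attribute (loss curves, epochs run, restarts).
#' @export
train_deep <- function(features, labels, spec, config = training_config()) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (min(table(y)) < 2L) stop("need at least 2 cases per class")
  X <- t(as.matrix(features))  # d x n
  if (nrow(X) != spec$input_dim)
    stop("feature dimension ", nrow(X), " does not match the network's ",
         spec$input_dim)

  set.seed(config$seed)
  val <- .validation_split(y, config$validation_fraction)
  train <- setdiff(seq_along(y), val)
  inits <- lapply(seq_len(config$max_restarts + 1L), function(a) {
    s <- init_network(spec)
    list(W = s$weights, b = s$biases)
  })
  acts <- vapply(spec$activations, .act_code, integer(1))
  bn <- spec$activations == "relu_bn"

  res <- cpp_train_net(X, y, train - 1L, val - 1L, inits,
                       acts, bn,
                       config$learning_rate, config$adam_beta1,
                       config$adam_beta2, config$adam_eps,
                       config$batch_size, config$max_epochs,
                       config$min_epochs, config$probe_epochs,
                       config$patience,
                       as.double(derive_seed(config$seed, "batches")))
  if (!isTRUE(res$converged))
    stop("deep network training failed: validation error did not decrease ",
         "within the probe window in any of ", res$restarts_used,
         " initializations")
  spec$weights <- res$W
  spec$biases <- lapply(res$b, drop)
  spec$bn <- lapply(res$bn, function(z)
    if (is.null(z)) NULL else lapply(z, drop))
  attr(spec, "diagnostics") <- list(
    train_curve = res$train_curve, val_curve = res$val_curve,
    epochs_run = res$epochs_run, best_epoch = res$best_epoch,
    best_val_error = res$best_val_error,
    restarts_used = res$restarts_used,
    validation_cases = val)
  spec
}
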