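#' Fully connected network specification
#'
#' Defines the pyramid classifier network: per-layer widths (last = 2, the
#' concussion / non-injury pair), an activation schedule, and (optionally)
#' weights. The study-scale full-input network is 2000-1000-500-250-2 and
#' the reduced network for selected features is 500-250-125-60-2; the
#' default schedule is ReLU + batch normalization on layer 1, ReLU on layers
#' 2-3, sigmoid on layer 4, and identity on the output layer, which feeds a
#' softmax.
#'
#' @param input_dim number of input features.
#' @param layer_widths integer widths, last entry must be 2.
#' @param activations character per layer: `"relu_bn"`, `"relu"`,
#'   `"sigmoid"`, `"identity"`.
#' @param weights,biases optional lists of matrices/vectors (`W[[l]]` is
#'   `width_l x width_{l-1}`).
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input_dim, layer_widths,
                         activations = default_activations(length(layer_widths)),
                         weights = NULL, biases = NULL) {
  L <- length(layer_widths)
  if (layer_widths[L] != 2L) stop("the output layer must have width 2")
  if (length(activations) != L)
    stop("need one activation per layer")
  ok <- activations %in% c("relu_bn", "relu", "sigmoid", "identity")
  if (!all(ok)) stop("unknown activation: ", activations[!ok][1])
  fan_in <- c(input_dim, layer_widths[-L])
  if (!is.null(weights)) {
    for (l in seq_len(L)) {
      if (!all(dim(weights[[l]]) == c(layer_widths[l], fan_in[l])))
        stop("W[[", l, "]] must be ", layer_widths[l], " x ", fan_in[l])
      if (length(biases[[l]]) != layer_widths[l])
        stop("b[[", l, "]] must have length ", layer_widths[l])
    }
  }
  structure(list(input_dim = as.integer(input_dim),
                 layer_widths = as.integer(layer_widths),
                 activations = activations,
                 weights = weights, biases = biases,
                 bn = NULL),
            class = "network_spec")
}

#' @rdname network_spec
#' @param n_layers number of layers.
#' @export
default_activations <- function(n_layers) {
  a <- rep("relu", n_layers)
  a[1] <- "relu_bn"
  if (n_layers >= 2) a[n_layers - 1] <- "sigmoid"
  a[n_layers] <- "identity"
  a
}

#' Pyramid layer widths for a given input size
#'
#' Study-scale presets reproduce the reference architectures
#' (2000-1000-500-250-2 full; 500-250-125-60-2 reduced). Desk-scale presets
#' are width-scaled versions of the same halving pyramid, sized for
#' synthetic grids of a few thousand WM voxels.
#'
#' @param input_dim number of input features.
#' @param scale `"desk"` or `"paper"`.
#' @param reduced logical: network for a selected (reduced) feature set?
#' @return Integer vector of layer widths ending in 2.
#' @export
pyramid_widths <- function(input_dim, scale = c("desk", "paper"),
                           reduced = input_dim <= 1000) {
  scale <- match.arg(scale)
  if (scale == "paper") {
    if (reduced) c(500L, 250L, 125L, 60L, 2L)
    else c(2000L, 1000L, 500L, 250L, 2L)
  } else {
    if (reduced) c(32L, 16L, 8L, 4L, 2L) else c(64L, 32L, 16L, 8L, 2L)
  }
}

#' Parameter count of a pyramid network
#'
#' @param input_dim input feature count.
#' @param layer_widths widths per layer (last = 2).
#' @param include_bias count bias entries too? The full network's quoted
#'   total (over 1.31e8) includes biases; the reduced network's quoted
#'   4.85e5 counts weight entries.
#' @return Total number of independent parameters.
#' @export
count_parameters <- function(input_dim, layer_widths, include_bias = TRUE) {
  fan_in <- c(input_dim, layer_widths[-length(layer_widths)])
  total <- sum(as.double(layer_widths) * fan_in)
  if (include_bias) total <- total + sum(layer_widths)
  total
}

.act_code <- function(a) {
  c(relu_bn = 1L, relu = 1L, sigmoid = 2L, identity = 0L)[[a]]
}

#' Initialize network weights
#'
#' He initialization for ReLU layers, Glorot for sigmoid/identity; biases
#' start at zero. Draws from the current RNG state.
#'
#' @param spec a [network_spec()].
#' @return The spec with `weights` and `biases` filled in.
#' @export
init_network <- function(spec) {
  L <- length(spec$layer_widths)
  fan_in <- c(spec$input_dim, spec$layer_widths[-L])
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sdv <- if (spec$activations[l] %in% c("relu", "relu_bn"))
      sqrt(2 / fan_in[l]) else sqrt(1 / fan_in[l])
    W[[l]] <- matrix(rnorm(spec$layer_widths[l] * fan_in[l], sd = sdv),
                     nrow = spec$layer_widths[l])
    b[[l]] <- rep(0, spec$layer_widths[l])
  }
  spec$weights <- W
  spec$biases <- b
  spec
}

#' Forward pass of the network
#'
#' Applies the per-layer affine transform and activation schedule, then a
#' softmax over the two outputs, returning `(p1, p2)` with `p1` the
#' concussion probability; `p1 + p2 = 1`. Batch-normalized layers use the
#' stored running statistics (inference mode); a spec without trained batch
#' statistics falls back to identity normalization.
#'
#' @param spec a fitted [network_spec()] (weights present).
#' @param x0 numeric vector of length `input_dim`, or a matrix with one case
#'   per row.
#' @return For a vector input, named numeric `c(p1, p2)`; for a matrix, an
#'   `n x 2` matrix of probabilities.
#' @export
forward <- function(spec, x0) {
  if (is.null(spec$weights)) stop("network has no weights; fit or init first")
  single <- is.null(dim(x0))
  X <- if (single) matrix(as.numeric(x0), ncol = 1)
       else t(as.matrix(x0))
  if (nrow(X) != spec$input_dim)
    stop("input has ", nrow(X), " features; the network expects ",
         spec$input_dim)
  L <- length(spec$layer_widths)
  A <- X
  for (l in seq_len(L)) {
    Z <- spec$weights[[l]] %*% A + spec$biases[[l]]
    if (spec$activations[l] == "relu_bn" && !is.null(spec$bn) &&
        !is.null(spec$bn[[l]])) {
      bn <- spec$bn[[l]]
      Z <- (Z - bn$mean) / sqrt(bn$var + 1e-5) * bn$gamma + bn$beta
    }
    A <- switch(spec$activations[l],
                relu = , relu_bn = pmax(Z, 0),
                sigmoid = plogis(Z),
                identity = Z)
  }
  # softmax over the two output units, numerically stabilized
  A <- A - rep(apply(A, 2, max), each = 2)
  E <- exp(A)
  P <- E / rep(colSums(E), each = 2)
  if (single) c(p1 = P[1, 1], p2 = P[2, 1])
  else {
    out <- t(P)
    colnames(out) <- c("p1", "p2")
    out
  }
}
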