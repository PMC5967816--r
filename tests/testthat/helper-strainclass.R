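# shared fixtures (generated in code) and independent oracles

.fixture_env <- new.env(parent = emptyenv())

# small 16^3 study for fast unit tests
tiny_config <- function(effect_size = 3, n_cases = 24L, n_concussion = 10L,
                        seed = 7L, ...) {
  generator_config(grid_shape = c(16L, 16L, 16L), n_cases = n_cases,
                   n_concussion = n_concussion, effect_size = effect_size,
                   seed = seed, ...)
}

tiny_dataset <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_dataset(tiny_config(...))
  .fixture_env[[key]]
}

# the default desk-scale study (58 cases, 32^3), shared across test files
default_dataset <- function() {
  if (is.null(.fixture_env$default))
    .fixture_env$default <- generate_dataset(generator_config())
  .fixture_env$default
}

# exhaustive pairwise-concordance AUC oracle (ties count one half)
brute_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# direct evaluation of the F-score formula for one feature column
brute_fscore <- function(x, y) {
  m1 <- mean(x[y == 1]); m0 <- mean(x[y == 0]); m <- mean(x)
  num <- (m1 - m)^2 + (m0 - m)^2
  den <- var(x[y == 1]) + var(x[y == 0])
  if (den == 0) return(if (num > 0) Inf else 0)
  num / den
}

# share of a mask's voxels lying inside the planted ROIs
planted_share <- function(indices, dataset) {
  gt <- ground_truth(dataset$provenance$config, dataset)
  mean(indices %in% gt$planted_feature_index)
}

planted_fraction <- function(dataset) {
  gt <- ground_truth(dataset$provenance$config, dataset)
  length(gt$planted_feature_index) / dataset$grid$n_wm
}
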