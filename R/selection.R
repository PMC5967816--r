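#' Feature selection configuration
#'
#' @param method `"none"`, `"fscore"` (retain the top fraction of voxels by
#'   F-score) or `"rfvote"` (random-forest voting).
#' @param fraction F-score retention fraction (default 0.04, i.e. ~4% of WM
#'   voxels; the count is `round(fraction * N_WM)`).
#' @param n_runs number of randomly initialized RF runs for voting (desk
#'   default 200; the study-scale value is 5000).
#' @param per_run_fraction fraction of voxels credited one vote per run
#'   (default 0.01).
#' @param final_fraction fraction of voxels retained by final vote count
#'   (default 0.01).
#' @param n_trees,max_depth forest shape used inside the voting runs (shared
#'   with the downstream RF classifier's selected-features config).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(method = c("none", "fscore", "rfvote"),
                             fraction = 0.04,
                             n_runs = 200L, per_run_fraction = 0.01,
                             final_fraction = 0.01,
                             n_trees = 75L, max_depth = 12L) {
  method <- match.arg(method)
  structure(list(method = method, fraction = fraction,
                 n_runs = as.integer(n_runs),
                 per_run_fraction = per_run_fraction,
                 final_fraction = final_fraction,
                 n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth)),
            class = "selection_config")
}

#' F-score of every voxel feature
#'
#' For voxel `j` with class means `m1, m0`, overall mean `m`, and within-class
#' sample variances `s1^2, s0^2`:
#' `F_j = ((m1 - m)^2 + (m0 - m)^2) / (s1^2 + s0^2)`.
#' Voxels constant across all cases score 0; voxels constant within both
#' classes but differing between them (infinite ratio) are assigned the
#' maximum finite score plus one, so they rank first.
#'
#' @param features case-by-voxel numeric matrix.
#' @param labels binary per case.
#' @return Non-negative finite score per voxel.
#' @export
fscore_rank <- function(features, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (min(table(y)) < 2L) stop("need at least 2 cases per class")
  x1 <- features[y == 1L, , drop = FALSE]
  x0 <- features[y == 0L, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  m <- colMeans(features)
  v1 <- .colVars(x1, m1); v0 <- .colVars(x0, m0)
  num <- (m1 - m)^2 + (m0 - m)^2
  den <- v1 + v0
  sc <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  if (any(is.infinite(sc))) {
    top <- suppressWarnings(max(sc[is.finite(sc)]))
    if (!is.finite(top)) top <- 0
    sc[is.infinite(sc)] <- top + 1
  }
  sc
}

.colVars <- function(x, mu) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  colSums((x - rep(mu, each = n))^2) / (n - 1)
}

#' Retain the top-scoring fraction of voxels
#'
#' Keeps `round(fraction * N)` voxels with the highest scores; ties at the
#' cutoff are broken in favor of the lowest voxel index.
#'
#' @param scores per-voxel scores.
#' @param fraction retention fraction in `(0, 1]`.
#' @param method,fold_id metadata stored in the mask.
#' @return A `selection_mask`: list with `indices` (sorted feature indices),
#'   `method`, `fold_id`, `n_features`.
#' @export
select_top_fraction <- function(scores, fraction, method = "fscore",
                                fold_id = NA_integer_) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  n <- length(scores)
  k <- max(1L, round(fraction * n))
  ord <- order(-scores, seq_len(n))
  structure(list(indices = sort(ord[seq_len(k)]), method = method,
                 fold_id = fold_id, n_features = n),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("selection_mask (%s): %d of %d voxels\n",
              x$method, length(x$indices), x$n_features))
  invisible(x)
}

#' Random-forest voting feature selection
#'
#' Runs `n_runs` randomly initialized random forests; after each run the top
#' `per_run_fraction` of voxels by mean impurity-decrease (Gini) importance
#' each receive one unweighted vote. The final mask is the top
#' `final_fraction` of voxels by vote count (ties broken by lowest index).
#' Deterministic given `seed`.
#'
#' @param features case-by-voxel matrix.
#' @param labels binary per case.
#' @param config a [selection_config()] (fields `n_runs`,
#'   `per_run_fraction`, `final_fraction`, `n_trees`, `max_depth`).
#' @param seed integer seed.
#' @param fold_id stored in the mask.
#' @return A `selection_mask`, with the vote counts attached as
#'   attribute `votes`.
#' @export
rf_vote_select <- function(features, labels, config = selection_config("rfvote"),
                           seed = 1L, fold_id = NA_integer_) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (config$n_runs < 1L) stop("n_runs must be >= 1")
  p <- ncol(features)
  k_run <- max(1L, round(config$per_run_fraction * p))
  votes <- integer(p)
  yf <- factor(y, levels = c(0L, 1L))
  xm <- as.matrix(features)
  colnames(xm) <- paste0("v", seq_len(ncol(xm)))
  for (r in seq_len(config$n_runs)) {
    fit <- ranger::ranger(x = xm, y = yf,
                          num.trees = config$n_trees,
                          max.depth = config$max_depth,
                          importance = "impurity",
                          seed = derive_seed(seed, "rfvote", r),
                          num.threads = 1L, verbose = FALSE)
    imp <- fit$variable.importance
    top <- order(-imp, seq_len(p))[seq_len(k_run)]
    votes[top] <- votes[top] + 1L
  }
  mask <- select_top_fraction(votes, config$final_fraction,
                              method = "rfvote", fold_id = fold_id)
  attr(mask, "votes") <- votes
  mask
}

#' Dispatch feature selection per the configuration
#'
#' @param features training case-by-voxel matrix (held-out case excluded by
#'   the caller; selection never sees it).
#' @param labels binary training labels.
#' @param config a [selection_config()].
#' @param seed integer seed (used by `"rfvote"`).
#' @param fold_id stored in the mask.
#' @return A `selection_mask`, or `NULL` for `method = "none"`.
#' @export
select_features <- function(features, labels, config, seed = 1L,
                            fold_id = NA_integer_) {
  if (is.null(config) || config$method == "none") return(NULL)
  switch(config$method,
         fscore = select_top_fraction(fscore_rank(features, labels),
                                      config$fraction, method = "fscore",
                                      fold_id = fold_id),
         rfvote = rf_vote_select(features, labels, config, seed = seed,
                                 fold_id = fold_id))
}

#' Cross-fold selection probability map
#'
#' Per-voxel frequency of being selected as a feature across the
#' cross-validation folds; with 58 folds, the conventional display threshold
#' of a frequency greater than 0.5 corresponds to selection in at least 29
#' folds.
#'
#' @param masks list of `selection_mask` objects, one per fold, all from the
#'   same method.
#' @param grid the shared [volume_grid()].
#' @return Object of class `selection_probability_map`: `frequency` (per WM
#'   voxel, in canonical order), `n_folds`, `method`.
#' @export
selection_probability_map <- function(masks, grid) {
  masks <- Filter(Negate(is.null), masks)
  if (length(masks) == 0L) stop("no selection masks supplied")
  methods <- unique(vapply(masks, function(m) m$method, character(1)))
  if (length(methods) > 1L)
    stop("masks mix selection methods: ", paste(methods, collapse = ", "))
  counts <- integer(grid$n_wm)
  for (m in masks) {
    if (m$n_features != grid$n_wm)
      stop("mask feature space does not match the grid")
    counts[m$indices] <- counts[m$indices] + 1L
  }
  structure(list(frequency = counts / length(masks),
                 n_folds = length(masks), method = methods),
            class = "selection_probability_map")
}

#' Threshold a selection probability map for display
#'
#' @param map a [selection_probability_map()].
#' @param min_frequency display threshold (default 0.5: shown voxels were
#'   selected in more than half the folds).
#' @return Integer vector of WM feature indices with
#'   `frequency > min_frequency`.
#' @export
threshold_map <- function(map, min_frequency = 0.5) {
  which(map$frequency > min_frequency)
}
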