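test_that("F-scores match a direct evaluation of the formula", {
  # 4-case, 2-voxel hand example: voxel 2 is within-class constant
  x <- cbind(c(2, 4, 1, 3), c(5, 5, 1, 1))
  y <- c(1, 1, 0, 0)
  sc <- fscore_rank(x, y)
  expect_equal(sc[1], brute_fscore(x[, 1], y))   # 0.5 / 4
  expect_equal(sc[1], 0.125)
  expect_gt(sc[2], sc[1])  # maximum-score convention ranks it first
  expect_true(all(is.finite(sc)))

  # identical across all cases -> 0
  x0 <- cbind(rep(0.3, 4), c(2, 4, 1, 3))
  expect_equal(fscore_rank(x0, y)[1], 0)

  # permutation of case order leaves scores unchanged
  set.seed(4)
  xm <- matrix(rnorm(8 * 20), 8)
  ym <- rep(c(1, 0), each = 4)
  perm <- sample(8)
  expect_equal(fscore_rank(xm, ym), fscore_rank(xm[perm, ], ym[perm]))

  # random instances agree with the brute-force oracle
  for (j in sample(20, 5))
    expect_equal(fscore_rank(xm, ym)[j], brute_fscore(xm[, j], ym))

  expect_error(fscore_rank(xm, rep(1, 8)), "both classes")
})

test_that("top-fraction retention rounds, bounds and breaks ties by index", {
  sc <- c(5, 1, 4, 2, 3)
  expect_equal(select_top_fraction(sc, 1.0)$indices, 1:5)
  expect_error(select_top_fraction(sc, 0), "fraction")
  expect_error(select_top_fraction(sc, 1.5), "fraction")

  # the study-scale arithmetic: 1% of 64272 WM voxels is 643
  big <- rep(1, 64272)
  expect_length(select_top_fraction(big, 0.01)$indices, 643)
  expect_length(select_top_fraction(big, 0.04)$indices, round(0.04 * 64272))

  # all-equal scores: ties resolved toward the lowest indices
  expect_equal(select_top_fraction(rep(7, 10), 0.5)$indices, 1:5)
})

test_that("RF voting with one run collapses to that run's importance ranking", {
  ds <- tiny_dataset()
  x <- dataset_features(ds); y <- dataset_labels(ds)
  cfg <- selection_config("rfvote", n_runs = 1L, n_trees = 25L,
                          max_depth = 6L)
  m1 <- rf_vote_select(x, y, cfg, seed = 13)
  xm <- x; colnames(xm) <- paste0("v", seq_len(ncol(xm)))
  ref <- ranger::ranger(x = xm, y = factor(y, levels = c(0, 1)),
                        num.trees = 25L, max.depth = 6L,
                        importance = "impurity",
                        seed = derive_seed(13, "rfvote", 1),
                        num.threads = 1L, verbose = FALSE)
  k <- max(1L, round(cfg$per_run_fraction * ncol(x)))
  top <- sort(order(-ref$variable.importance, seq_len(ncol(x)))[seq_len(k)])
  # the single run's vote winners are exactly its top-importance voxels
  votes <- attr(m1, "votes")
  expect_setequal(which(votes == 1L), top)

  m2 <- rf_vote_select(x, y, cfg, seed = 14)
  expect_length(m2$indices, length(m1$indices))  # size contract
  m1b <- rf_vote_select(x, y, cfg, seed = 13)
  expect_identical(m1$indices, m1b$indices)      # determinism
})

test_that("RF voting recovers planted voxels far above chance", {
  ds <- default_dataset()
  x <- dataset_features(ds); y <- dataset_labels(ds)
  cfg <- selection_config("rfvote", n_runs = 25L)
  mask <- rf_vote_select(x, y, cfg, seed = 5)
  share <- planted_share(mask$indices, ds)
  chance <- planted_fraction(ds)
  expect_lt(chance, 0.1)
  expect_gte(share, 0.5)

  # under label permutation the enrichment collapses toward chance
  perm_shares <- vapply(1:5, function(s) {
    set.seed(600 + s)
    yp <- sample(y)
    m <- rf_vote_select(x, yp, selection_config("rfvote", n_runs = 10L),
                        seed = 700 + s)
    planted_share(m$indices, ds)
  }, numeric(1))
  expect_lt(mean(perm_shares), share / 2)
})

test_that("selection probability maps count per-fold frequencies", {
  g <- tiny_dataset()$grid
  n_wm <- g$n_wm
  mk <- function(idx, fold) structure(
    list(indices = idx, method = "fscore", fold_id = fold,
         n_features = n_wm), class = "selection_mask")
  masks <- lapply(1:58, function(k)
    mk(if (k <= 29) c(1L, 2L) else 2L, k))
  map <- selection_probability_map(masks, g)
  expect_equal(map$frequency[1], 0.5)  # 29 of 58 folds
  expect_equal(map$frequency[2], 1.0)
  expect_equal(map$frequency[3], 0.0)
  expect_true(all(abs(map$frequency * map$n_folds -
                        round(map$frequency * map$n_folds)) < 1e-9))
  # strict > 0.5 display threshold excludes the 29/58 voxel
  expect_equal(threshold_map(map), 2L)

  same <- lapply(1:4, function(k) mk(c(5L, 9L), k))
  map2 <- selection_probability_map(same, g)
  expect_equal(which(map2$frequency == 1), c(5L, 9L))
  expect_equal(sum(map2$frequency), 2)

  mixed <- c(masks[1:3], list(mk(1L, 4)))
  mixed[[4]]$method <- "rfvote"
  expect_error(selection_probability_map(mixed, g), "mix")
})
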