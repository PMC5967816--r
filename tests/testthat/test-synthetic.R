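test_that("make_grid is deterministic with sensible WM and ROI census", {
  cfg <- generator_config()
  g1 <- make_grid(cfg)
  g2 <- make_grid(cfg)
  expect_identical(g1$wm_mask, g2$wm_mask)
  expect_identical(g1$roi_labels, g2$roi_labels)
  expect_gt(g1$n_wm, 2000)
  expect_lt(g1$n_wm, 8000)
  census <- table(g1$roi_labels[g1$roi_labels > 0])
  expect_setequal(names(census), as.character(1:7))
  expect_true(all(census >= 20))
  expect_error(make_grid(generator_config(grid_shape = c(4, 4, 4))),
               "each >= 8")
})

test_that("generated datasets honor the structural invariants", {
  ds <- tiny_dataset()
  g <- ds$grid
  cfg <- tiny_config()
  expect_equal(sum(dataset_labels(ds)), cfg$n_concussion)
  for (cc in ds$cases[c(1, 5, 12)]) {
    expect_true(all(cc$fiber_strain >= 0))
    expect_true(all(cc$fiber_strain <= cc$mps + 1e-12))
    expect_true(all(cc$fiber_strain[!g$wm_mask] == 0))
    expect_true(all(cc$mps[!g$brain_mask] == 0))
    expect_true(all(cc$peak_ang_vel >= 0))
  }
})

test_that("the generator is deterministic given its config", {
  d1 <- generate_dataset(tiny_config(seed = 41L))
  d2 <- generate_dataset(tiny_config(seed = 41L))
  expect_identical(dataset_features(d1), dataset_features(d2))
  expect_identical(dataset_labels(d1), dataset_labels(d2))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  d3 <- generate_dataset(tiny_config(seed = 42L))
  expect_false(identical(dataset_features(d1), dataset_features(d3)))
})

test_that("defaults reproduce the 25/33 class design", {
  ds <- default_dataset()
  y <- dataset_labels(ds)
  expect_equal(sum(y == 1), 25)
  expect_equal(sum(y == 0), 33)
})

test_that("a zero effect size yields a null label-strain association", {
  rs <- vapply(1:20, function(s) {
    ds <- generate_dataset(generator_config(
      grid_shape = c(16L, 16L, 16L), effect_size = 0, seed = 100L + s))
    gt <- ground_truth(ds$provenance$config, ds)
    m <- rowMeans(dataset_features(ds)[, gt$planted_feature_index])
    cor(m, dataset_labels(ds))
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.15)
})

test_that("effect size 2 separates classes with AUC >= 0.9 on average", {
  aucs <- vapply(1:10, function(s) {
    ds <- generate_dataset(generator_config(
      grid_shape = c(16L, 16L, 16L), effect_size = 2, seed = 300L + s))
    gt <- ground_truth(ds$provenance$config, ds)
    m <- rowMeans(dataset_features(ds)[, gt$planted_feature_index])
    roc_auc(m, dataset_labels(ds))$auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.9)
})

test_that("kinematics-severity correlation rises with the coupling", {
  mean_cor <- vapply(c(0, 0.5, 1), function(kap) {
    mean(vapply(1:10, function(s) {
      ds <- generate_dataset(generator_config(
        grid_shape = c(16L, 16L, 16L), kinematics_coupling = kap,
        seed = 500L + s))
      gt <- ground_truth(ds$provenance$config, ds)
      wmag <- vapply(ds$cases, function(cc) sqrt(sum(cc$peak_ang_vel^2)),
                     numeric(1))
      cor(wmag, gt$severity)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cor) > 0))
  expect_gt(mean_cor[3], 0.9)
  expect_lt(abs(mean_cor[1]), 0.25)
})

test_that("ground truth exposes the planted structure", {
  ds <- tiny_dataset()
  cfg <- tiny_config()
  gt <- ground_truth(cfg, ds)
  g <- ds$grid
  expect_true(all(gt$planted_voxel_index %in% g$wm_index))
  expect_setequal(gt$planted_feature_index,
                  roi_feature_index(g, cfg$planted_rois))
  expect_length(gt$severity, cfg$n_cases)
  plain <- strain_dataset(g, ds$cases, provenance = list())
  expect_error(ground_truth(cfg, plain), "not produced")
})
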