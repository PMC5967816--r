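test_that("BrIC matches its closed form and is positively homogeneous", {
  crit <- critical_velocities()
  expect_equal(compute_bric(c(30.4, 0, 0), crit), 1.0)
  expect_equal(compute_bric(c(0, 0, 0), crit), 0.0)
  expect_equal(compute_bric(c(30.4, 35.6, 23.5), crit), sqrt(3),
               tolerance = 1e-12)
  set.seed(1)
  for (i in 1:10) {
    w <- runif(3, 0, 50); cscale <- runif(1, 0, 3)
    expect_equal(compute_bric(cscale * w, crit),
                 cscale * compute_bric(w, crit), tolerance = 1e-12)
  }
  expect_error(compute_bric(c(-1, 0, 0), crit), "non-negative")
  expect_error(critical_velocities(wxc = -1), "positive")
})

test_that("CSDM counts the above-threshold volume fraction and is monotone", {
  g <- tiny_dataset()$grid
  shape <- g$shape
  region <- g$brain_mask
  mk_case <- function(mps_val) {
    mps <- array(0, shape); mps[region] <- mps_val
    fib <- array(0, shape)
    strain_case("c", fib, mps, c(1, 1, 1), 1, g)
  }
  expect_equal(compute_csdm(mk_case(0.3), region, 0.2), 1.0)
  expect_equal(compute_csdm(mk_case(0.1), region, 0.2), 0.0)

  idx <- which(region)
  half <- rep(0.1, length(idx))
  half[seq_len(floor(length(idx) / 2))] <- 0.3
  mps <- array(0, shape); mps[idx] <- half
  cc <- strain_case("h", array(0, shape), mps, c(1, 1, 1), 0, g)
  expect_equal(compute_csdm(cc, region, 0.2),
               floor(length(idx) / 2) / length(idx))

  # non-increasing in the threshold; 1 at threshold 0 on a positive region
  rnd <- array(0, shape); rnd[idx] <- runif(length(idx), 0.01, 0.5)
  cr <- strain_case("r", array(0, shape), rnd, c(1, 1, 1), 0, g)
  vals <- vapply(c(0, 0.1, 0.2, 0.3, 0.6), compute_csdm, numeric(1),
                 case = cr, region_mask = region)
  expect_equal(vals[1], 1.0)
  expect_true(all(diff(vals) <= 0))
  expect_error(compute_csdm(cr, array(FALSE, shape), 0.2), "empty")
})

test_that("peak ROI strain equals an exhaustive scan and implies the CSDM bound", {
  ds <- tiny_dataset()
  g <- ds$grid
  cc <- ds$cases[[3]]
  for (lab in c(1L, 2L, 6L)) {
    brute <- max(cc$fiber_strain[which(g$roi_labels == lab)])
    expect_equal(compute_peak_roi(cc, g, lab), brute)
  }
  expect_error(compute_peak_roi(cc, g, 99L), "no voxels")

  cc_mask <- g$roi_labels == 1L
  thr <- 0.05
  if (compute_csdm(cc, cc_mask, thr) > 0)
    expect_gt(max(cc$mps[cc_mask]), thr)

  shape <- g$shape
  zero <- strain_case("z", array(0, shape), array(0, shape), c(0, 0, 0), 0, g)
  expect_equal(compute_peak_roi(zero, g, 1L), 0.0)
  single <- array(0, shape)
  single[which(g$roi_labels == 1L)[1]] <- 0.4
  one <- strain_case("o", single, single, c(0, 0, 0), 1, g)
  expect_equal(compute_peak_roi(one, g, 1L), 0.4)
})

test_that("metric_table produces one row per case with all four metrics", {
  ds <- tiny_dataset()
  tb <- metric_table(ds)
  expect_equal(nrow(tb), length(ds$cases))
  expect_named(tb, c("case_id", "BrIC", "CSDM_WB", "CSDM_CC", "Peak_CC",
                     "label"))
  expect_true(all(tb$CSDM_WB >= 0 & tb$CSDM_WB <= 1))
  expect_true(all(tb$BrIC >= 0))
})

test_that("univariate logistic fitting handles the degenerate regimes", {
  # zero-variance metric: intercept-only model at the class prevalence
  y <- rep(c(1, 0), c(4, 6))
  m0 <- fit_univariate_logistic(rep(2.2, 10), y)
  expect_equal(m0$slope, 0)
  expect_equal(predict(m0, c(0, 5)), rep(0.4, 2), tolerance = 1e-9)

  # parameter recovery at n = 2000
  set.seed(11)
  x <- rnorm(2000)
  yy <- rbinom(2000, 1, plogis(-0.5 + 1.2 * x))
  fit <- fit_univariate_logistic(x, yy)
  expect_false(fit$separated)
  expect_lt(abs(fit$slope - 1.2) / 1.2, 0.1)

  # complete separation: flagged, finite ridge fallback
  xs <- c(1, 2, 3, 10, 11, 12)
  ys <- c(0, 0, 0, 1, 1, 1)
  sep <- fit_univariate_logistic(xs, ys)
  expect_true(sep$separated)
  expect_true(is.finite(sep$slope) && sep$slope > 0)

  expect_error(fit_univariate_logistic(1:5, rep(1, 5)), "both classes")
})

test_that("logistic predictions follow the inverse logit exactly", {
  m <- fit_univariate_logistic(c(0.1, 0.4, 0.2, 0.8, 0.9, 0.7),
                               c(0, 0, 0, 1, 1, 1) [c(1, 3, 2, 4, 6, 5)])
  grid_x <- seq(-3, 3, by = 0.25)
  expect_equal(predict_logistic(m, grid_x),
               1 / (1 + exp(-(m$intercept + m$slope * grid_x))))
  # logit zero at -intercept/slope
  expect_equal(predict_logistic(m, -m$intercept / m$slope), 0.5)
  # monotone when the slope is positive (non-strict at float saturation)
  if (m$slope > 0) {
    p <- predict_logistic(m, grid_x)
    expect_true(all(diff(p) >= 0))
    mid <- which(p > 0.4 & p < 0.6)
    if (length(mid) > 1) expect_true(all(diff(p[mid]) > 0))
  }
})
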