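# Projection, binarization, depth cropping, MESS.

test_that("projection reuses the ensemble committee consistently", {
  fx <- small_fitted()
  ens <- fx$ensemble; w <- fx$world
  map <- project_ensemble(ens, w)
  expect_true(all(map$suitability >= 0 & map$suitability <= 1))
  # projecting onto the training stack reproduces training-cell predictions
  direct <- seashift:::ensemble_predict(ens, as_tibble(w))
  expect_equal(map$suitability, direct)
  # an identity anomaly leaves the projection unchanged
  an1 <- tibble::tibble(cell = w$cell)
  for (p in stack_predictors(w)) an1[[p]] <- 1
  map_f <- project_ensemble(ens, apply_anomaly(w, an1))
  expect_equal(map_f$suitability, map$suitability)
  expect_error(project_ensemble(ens, toy_stack(5, 5)), "missing predictor")
})

test_that("binarization thresholds are stable across scenarios", {
  fx <- small_fitted()
  w <- fx$world
  map <- project_ensemble(fx$ensemble, w)
  rng <- binarize_map(map)
  thr <- attr(rng, "threshold")
  expect_true(all(map$suitability[match(rng$cell, map$cell)] >= thr))
  # future maps reuse the stored baseline threshold
  an <- make_anomaly(w, "rcp85", "far")
  map_f <- project_ensemble(fx$ensemble, apply_anomaly(w, an))
  expect_equal(attr(binarize_map(map_f), "threshold"), thr)
  # threshold 0 floods every sea cell
  all_in <- binarize_map(map, threshold = 0)
  expect_equal(nrow(all_in), nrow(w))
})

test_that("well-separated predictions give the same range for any mid threshold", {
  base <- tibble::tibble(cell = 1:20, row = 1L, col = 1:20,
                         suitability = rep(c(0.9, 0.1), each = 10))
  map <- structure(base, species_id = "s", scenario = "b", threshold = 0.5,
                   dims = c(1L, 20L), class = c("suitability_map", class(tibble::tibble())))
  picked <- lapply(c(0.11, 0.3, 0.5, 0.7, 0.9), function(t)
    binarize_map(map, threshold = t)$cell)
  for (p in picked) expect_equal(p, 1:10)
})

test_that("the depth window is [0.7 p5, 1.3 p95] of baseline depths", {
  depths <- seq(50, 400, length.out = 101)  # p5 = 67.5, p95 = 382.5... use exact
  q <- quantile(depths, c(0.05, 0.95), names = FALSE)
  w <- toy_stack(10, 10, depth = seq(10, 800, length.out = 100))
  rng <- toy_range(w, w$row, w$col)
  occ <- tibble::tibble(cell = w$cell[w$depth >= 50 & w$depth <= 400])
  crop <- depth_crop(rng, w, baseline_occurrences = occ)
  win <- attr(crop, "depth_window")
  occ_d <- w$depth[match(occ$cell, w$cell)]
  expect_equal(win, c(0.7 * quantile(occ_d, 0.05, names = FALSE),
                      1.3 * quantile(occ_d, 0.95, names = FALSE)))
  kept_d <- w$depth[match(crop$cell, w$cell)]
  expect_true(all(kept_d >= win[1] & kept_d <= win[2]))
  # the stated example: p5 = 50, p95 = 400 -> window [35, 520]
  crop2 <- depth_crop(rng, w, depths = c(rep(50, 10), rep(400, 10)))
  win2 <- attr(crop2, "depth_window")
  expect_equal(win2, c(35, 520))
  # a suitable cell at 600 m is removed under that window
  expect_false(any(w$depth[match(crop2$cell, w$cell)] > 520))
  expect_true(any(w$depth > 520))
  # idempotence
  crop3 <- depth_crop(crop2, w, depths = c(rep(50, 10), rep(400, 10)))
  expect_identical(crop3$cell, crop2$cell)
  # equal depths degenerate to [0.7 d, 1.3 d]
  crop4 <- depth_crop(rng, w, depths = rep(100, 5))
  expect_equal(attr(crop4, "depth_window"), c(70, 130))
  expect_error(depth_crop(rng, w, depths = numeric()), "depths")
})

test_that("MESS flags extrapolation and scores the training median 100", {
  train <- tibble::tibble(T_median = rep(seq(10, 20, length.out = 50), 2),
                          SAL_median = rep(seq(35, 39, length.out = 50), 2))
  w <- toy_stack(10, 10, layers = list(
    T_median = seq(5, 25, length.out = 100),
    SAL_median = rep(37, 100)))
  mg <- mess_grid(w, train)
  below <- w$T_median < 10
  expect_true(all(mg$mess[below] < 0))
  # training stack onto itself: nonnegative everywhere
  wt <- toy_stack(10, 10, layers = list(
    T_median = rep(seq(10, 20, length.out = 50), 2),
    SAL_median = rep(seq(35, 39, length.out = 50), 2)))
  expect_true(all(mess_grid(wt, train)$mess >= 0))
  # a cell at the median of every predictor scores 100 (even-sized sample)
  train2 <- tibble::tibble(T_median = c(1:50, 51:100))
  w2 <- toy_stack(10, 10, layers = list(T_median = rep(50.5, 100)))
  expect_true(all(mess_grid(w2, train2)$mess == 100))
  # similarity decreases monotonically as values leave the training range
  sweep <- toy_stack(10, 10, layers = list(T_median = seq(20, 40, length.out = 100)))
  ms <- mess_grid(sweep, train["T_median"])$mess
  out_of_range <- sweep$T_median > 20
  expect_true(all(diff(ms[out_of_range]) <= 0))
  # constant training predictor: 0 inside the point range, negative outside
  mg3 <- mess_grid(toy_stack(5, 5, layers = list(T_median = c(rep(7, 20), rep(9, 5)))),
                   tibble::tibble(T_median = rep(7, 10)))
  expect_true(all(mg3$mess[1:20] == 0))
  expect_true(all(mg3$mess[21:25] < 0))
})
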