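# Temporal aggregation, control-run detrending, anomaly ratios, regridding.

test_that("monthly aggregation computes median/min/max/range", {
  series <- tidyr::expand_grid(cell = 1:3, time = 1:12) |>
    dplyr::mutate(value = ifelse(cell == 1, 9 + time,          # 10..21
                                 ifelse(cell == 2, 7, NA_real_)))
  agg <- aggregate_monthly(series)
  r1 <- agg[agg$cell == 1, ]
  expect_equal(r1$median, 15.5)
  expect_equal(r1$min, 10); expect_equal(r1$max, 21); expect_equal(r1$range, 11)
  r2 <- agg[agg$cell == 2, ]   # constant series
  expect_equal(c(r2$median, r2$min, r2$max, r2$range), c(7, 7, 7, 0))
  expect_true(is.na(agg$median[agg$cell == 3]))  # all-missing cell
  expect_error(aggregate_monthly(series[series$time <= 6, ]), ">= 12")
})

test_that("aggregation matches a brute-force sort oracle on random cells", {
  set.seed(31)
  series <- tidyr::expand_grid(cell = 1:100, time = 1:24) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  agg <- aggregate_monthly(series)
  for (cl in sample(1:100, 20)) {
    v <- sort(series$value[series$cell == cl])
    expect_equal(agg$median[agg$cell == cl], (v[12] + v[13]) / 2)
    expect_equal(agg$min[agg$cell == cl], v[1])
    expect_equal(agg$range[agg$cell == cl], v[24] - v[1])
  }
  expect_true(all(agg$range >= 0))
  expect_true(all(agg$min <= agg$median & agg$median <= agg$max))
})

test_that("control detrending removes an imposed drift exactly", {
  t <- 1:36
  signal <- sin(t / 4)
  drift <- 0.01 * t
  scen <- tibble::tibble(cell = 1L, time = t, value = signal + drift)
  ctrl <- tibble::tibble(cell = 1L, time = t, value = 5 + drift)
  out <- detrend_with_control(scen, ctrl)
  # intercept anchored at the series start: output(t) = signal(t) + drift(1)
  expect_lt(max(abs(out$value - (signal + drift[1]))), 1e-9)
  # constant control leaves the input unchanged
  ctrl0 <- tibble::tibble(cell = 1L, time = t, value = rep(3, 36))
  expect_equal(detrend_with_control(scen, ctrl0)$value, scen$value)
  expect_error(detrend_with_control(scen[1:2, ], ctrl[1:2, ]), ">= 3")
})

test_that("per-cell detrend slope matches the closed-form OLS oracle", {
  set.seed(7)
  t <- 1:24
  cells <- 1:50
  ctrl <- tidyr::expand_grid(cell = cells, time = t) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  scen <- dplyr::mutate(ctrl, value = 0)
  out <- detrend_with_control(scen, ctrl)
  for (cl in cells) {
    v <- ctrl$value[ctrl$cell == cl]
    beta <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)  # closed form
    got <- out$value[out$cell == cl]
    # output = 0 - slope*(t - 1); recover slope from the fitted line
    expect_equal(unname(-coef(lm(got ~ t))[2]), beta, tolerance = 1e-10)
  }
  # detrending a series by itself leaves no linear trend
  self <- detrend_with_control(ctrl, ctrl)
  sl <- self |> dplyr::group_by(cell) |>
    dplyr::summarise(s = unname(coef(lm(value ~ time))[2]))
  expect_lt(max(abs(sl$s)), 1e-9)
})

test_that("anomaly ratio is future/present with a zero guard", {
  fut <- tibble::tibble(cell = 1:3, value = c(15.4, 10, 2))
  pre <- tibble::tibble(cell = 1:3, value = c(14.0, 10, 0))
  expect_warning(an <- anomaly_ratio(fut, pre), "1 cell")
  expect_equal(an$value[1], 1.1)
  expect_equal(an$value[2], 1)
  expect_true(is.na(an$value[3]))
  expect_equal(attr(an, "n_undefined"), 1L)
  attr(fut, "predictor") <- "T_median"; attr(pre, "predictor") <- "O2_median"
  expect_error(anomaly_ratio(fut, pre), "mismatch")
  # future == present gives an identically 1 anomaly
  same <- tibble::tibble(cell = 1:5, value = rnorm(5) + 10)
  expect_equal(anomaly_ratio(same, same)$value, rep(1, 5))
})

test_that("regridding: identity, constants, and exact 2x2 block means", {
  w <- toy_stack(4, 4, layers = list(T_median = as.numeric(1:16),
                                     SAND = rep(c(0.2, 0.4, 0.6, 0.8), 4)))
  expect_identical(regrid_stack(w, factor = 1), w)
  cg <- regrid_stack(w, factor = 2)
  expect_identical(stack_dims(cg), c(2L, 2L))
  # hand-computed area-weighted block means on the 4x4 toy grid
  m <- layer_matrix(w, "SAND")
  expect_equal(layer_matrix(cg, "SAND")[1, 1], mean(m[1:2, 1:2]))
  expect_equal(layer_matrix(cg, "SAND")[2, 2], mean(m[3:4, 3:4]))
  tm <- layer_matrix(w, "T_median")
  expect_equal(layer_matrix(cg, "T_median")[1, 2], mean(tm[1:2, 3:4]))
  # constant layers stay constant under coarsening and refinement
  wc <- toy_stack(4, 4, layers = list(T_median = rep(7, 16), SAND = rep(0.3, 16)))
  expect_true(all(regrid_stack(wc, factor = 2)$T_median == 7))
  rf <- regrid_stack(wc, refine = 2)
  expect_identical(stack_dims(rf), c(8L, 8L))
  expect_true(all(abs(rf$T_median - 7) < 1e-12))
  expect_true(all(rf$SAND == 0.3))
})

test_that("coarsening masks target cells with minority sea coverage", {
  # drop 3 of the 4 source cells of the upper-left block: < 50% sea
  w <- toy_stack(4, 4, layers = list(T_median = as.numeric(1:16)),
                 drop_cells = c(1L, 2L, 5L))
  cg <- regrid_stack(w, factor = 2)
  expect_false(any(cg$row == 1 & cg$col == 1))
  expect_equal(nrow(cg), 3L)
})
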