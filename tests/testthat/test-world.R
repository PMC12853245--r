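# Synthetic world, virtual species, occurrence sampling, anomaly forcing.

test_that("world generation is deterministic and rejects tiny grids", {
  w1 <- generate_world(50, 80, seed = 1)
  w2 <- generate_world(50, 80, seed = 1)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
  w3 <- generate_world(50, 80, seed = 2)
  expect_false(identical(w1$T_median, w3$T_median))
  expect_error(generate_world(10, 80), "rows and cols")
})

test_that("imposed gradients hold: T falls northward, O2 anti-correlates with T", {
  w <- generate_world(50, 80, seed = 1)
  north_row <- min(w$row); south_row <- max(w$row)
  expect_lt(mean(w$T_median[w$row == north_row]),
            mean(w$T_median[w$row == south_row]))
  expect_lt(cor(w$T_median, w$O2_median, method = "spearman"), 0)
  # spatial autocorrelation: neighbouring cells more alike than random pairs
  m <- layer_matrix(w, "T_median")
  nbr_diff <- abs(m[-1, ] - m[-nrow(m), ])
  rand_diff <- abs(sample(w$T_median) - w$T_median)
  expect_lt(mean(nbr_diff, na.rm = TRUE), mean(rand_diff) / 2)
})

test_that("virtual species suitability follows its response product", {
  w <- generate_world(40, 40, seed = 4)
  # optimum far above the warmest cell: Gaussian response at offset >= 10
  # with sd 1.5 is < exp(-10^2 / (2*1.5^2)) << 0.05
  expect_warning(
    sp_hot <- make_virtual_species(w, "hot", max(w$T_median) + 10, breadth = 1.5),
    "outside world range")
  expect_true(sp_hot$out_of_range)
  expect_lt(max(sp_hot$suitability$suitability), 0.05)
  # flat responses on all predictors: suitability 1 on all sea cells
  flat <- lapply(stack_predictors(w), function(p) list(type = "flat"))
  names(flat) <- stack_predictors(w)
  sp_flat <- make_virtual_species(w, "flat", responses = flat)
  expect_true(all(sp_flat$suitability$suitability == 1))
  # land cells carry suitability 0 in the full-grid matrix
  m <- suitability_matrix(sp_flat, w)
  land <- !stack_mask(w)
  expect_true(any(land))
  expect_true(all(m[land] == 0))
  expect_error(make_virtual_species(w, "bad", 18, breadth = -1), "breadth")
})

test_that("occurrence sampling respects support, bias and determinism", {
  w <- toy_stack(10, 10)
  # species suitable on exactly 30 cells
  cells30 <- w$cell[seq_len(30)]
  sp <- make_virtual_species(w, "s", responses = list(T_median = list(type = "flat")))
  sp$suitability$suitability <- as.numeric(sp$suitability$cell %in% cells30)
  occ <- sample_occurrences(sp, w, 30, seed = 1)
  expect_setequal(occ$cell, cells30)
  expect_error(sample_occurrences(sp, w, 0), "n must be")
  # same seed, same draw
  o1 <- sample_occurrences(sp, w, 10, seed = 9)
  o2 <- sample_occurrences(sp, w, 10, seed = 9)
  expect_identical(o1, o2)
  # fewer positive-weight cells than n: all returned with a warning
  expect_warning(o3 <- sample_occurrences(sp, w, 60, seed = 1), "positive weight")
  expect_setequal(o3$cell, cells30)
})

test_that("doubled sampling bias doubles the sampled share (binomial bounds)", {
  w <- toy_stack(40, 50)
  sp <- make_virtual_species(w, "s", responses = list(T_median = list(type = "flat")))
  in_a <- w$col <= 25
  bias <- tibble::tibble(cell = w$cell, bias = ifelse(in_a, 2, 1))
  # expected share in A = 2/3; 2000 draws without replacement from 2000
  # cells would exhaust the grid, so draw 40 per replicate over 50 seeds
  hits <- 0L; n_tot <- 0L
  for (s in 1:50) {
    occ <- sample_occurrences(sp, w, 40, bias = bias, seed = s)
    hits <- hits + sum(occ$cell %in% w$cell[in_a])
    n_tot <- n_tot + nrow(occ)
  }
  bounds <- qbinom(c(0.005, 0.995), n_tot, 2 / 3)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("anomaly forcing is multiplicative, shape-checked and named", {
  w <- toy_stack(20, 20, layers = list(T_median = rep(15, 400),
                                       O2_median = rep(200, 400)))
  an <- tibble::tibble(cell = w$cell, T_median = 1.1, O2_median = 0.95)
  fut <- apply_anomaly(w, an)
  expect_equal(fut$T_median, rep(15 * 1.1, nrow(w)))
  expect_equal(mean(fut$O2_median), 0.95 * mean(w$O2_median))
  # identity anomaly: future equals baseline
  an1 <- tibble::tibble(cell = w$cell, T_median = 1, O2_median = 1)
  expect_equal(as.data.frame(apply_anomaly(w, an1))[stack_predictors(w)],
               as.data.frame(w)[stack_predictors(w)])
  expect_error(apply_anomaly(w, an[, c("cell", "T_median")]), "O2_median")
  an_bad <- an; an_bad$T_median <- -1
  expect_error(apply_anomaly(w, an_bad), "> 0")
})

test_that("warming moves the true centroid of cold-adapted species north", {
  w <- generate_world(60, 100, seed = 42)
  med_t <- median(w$T_median)
  fut <- apply_anomaly(w, make_anomaly(w, "rcp85", "far"))
  expect_true(all(make_anomaly(w, "rcp85", "far")$T_median > 1))
  for (opt in c(16.5, 17.5, 18.5)) {
    expect_lt(opt, med_t)  # genuinely cold-adapted in this world
    sp <- make_virtual_species(w, paste0("c", opt), opt, breadth = 1.5)
    base <- true_range_metrics(sp, w)
    shifted <- true_range_metrics(sp, fut)
    expect_gt(shifted$LAT, base$LAT)
  }
})
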