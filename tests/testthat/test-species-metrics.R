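# Range metrics, fragmentation, shift deltas, EIVs, correlation screen.

test_that("range metrics are area sums and area-weighted means", {
  w <- toy_stack(10, 10, depth = rep(c(100, 300), 50))
  rng <- toy_range(w, rows = rep(1:5, each = 2), cols = rep(1:2, 5))
  m <- range_metrics(rng, w)
  expect_equal(m$RANGE, 10)
  # equal-area cells at two latitudes average midway
  r2 <- toy_range(w, rows = c(3, 5), cols = c(1, 1))  # lat 7.5 and 5.5
  m2 <- range_metrics(r2, w)
  expect_equal(m2$LAT, mean(c(10 - 3 + 0.5, 10 - 5 + 0.5)))
  d <- w$depth[match(r2$cell, w$cell)]
  expect_equal(m2$DEPTH, mean(d))
  # cell areas scale with cell size but dRANGE does not
  w2 <- toy_stack(10, 10, cell_km = 2)
  m_small <- range_metrics(toy_range(w2, 1:3, rep(1, 3)), w2)
  expect_equal(m_small$RANGE, 3 * 4)
  # empty range: extinction
  e <- range_metrics(toy_range(w, integer(), integer()), w)
  expect_true(e$extinct); expect_true(is.na(e$LAT))
})

test_that("fragmentation measures mean edge-to-edge sea distance between clumps", {
  w <- toy_stack(9, 9)
  # single clump: FRAG 0 by convention
  one <- fragmentation(toy_range(w, c(2, 2, 3), c(2, 3, 2)), w)
  expect_equal(one$n_clumps, 1L); expect_equal(one$FRAG, 0)
  # two 1-cell clumps with a 3-cell sea gap: edge-to-edge distance 3
  two <- fragmentation(toy_range(w, c(5, 5), c(1, 5)), w)
  expect_equal(two$n_clumps, 2L)
  expect_equal(two$FRAG, 3)
  # adjacent-but-diagonal clumps under rook adjacency are distance-1 apart
  diagn <- fragmentation(toy_range(w, c(4, 5), c(4, 5)), w)
  expect_equal(diagn$n_clumps, 2L)
  expect_equal(diagn$FRAG, 1)
  # queen connectivity merges them
  q <- fragmentation(toy_range(w, c(4, 5), c(4, 5)), w, connectivity = 8)
  expect_equal(q$n_clumps, 1L)
  # three clumps: mean over all unordered pairs, BFS oracle by hand
  thr <- fragmentation(toy_range(w, c(1, 1, 1), c(1, 4, 9)), w)
  expect_equal(thr$FRAG, mean(c(2, 4, 7)))
})

test_that("land walls force paths through the corridor", {
  # a vertical wall at col 5 with one gap at row 9
  wall <- (seq_len(9) - 1) * 9 + 5          # cells (1..9, 5)
  w <- toy_stack(9, 9, drop_cells = wall[1:8])
  rng <- toy_range(w, c(1, 1), c(4, 6))     # either side of the wall
  fr <- fragmentation(rng, w)
  # straight-line gap is 1 cell; the sea path detours through row 9
  expect_equal(fr$n_clumps, 2L)
  expect_gt(fr$FRAG, 1)
  # BFS oracle: down 8, across 2, up 8 => 18 steps - 1 edge-to-edge
  expect_equal(fr$FRAG, 17)
  # fully walled-off clumps are excluded with a warning
  w2 <- toy_stack(9, 9, drop_cells = wall)
  expect_warning(fr2 <- fragmentation(toy_range(w2, c(1, 1), c(4, 6)), w2),
                 "no sea path")
  expect_equal(fr2$FRAG, 0)
  expect_equal(fr2$unreachable_pairs, 1L)
})

test_that("shift metrics: relative range change, absolute others, extinction", {
  base <- tibble::tibble(species_id = "s", scenario = "b", n_cells = 100L,
                         RANGE = 100, LAT = 40, DEPTH = 200, FRAG = 5,
                         extinct = FALSE)
  fut <- dplyr::mutate(base, scenario = "f", n_cells = 60L, RANGE = 60,
                       LAT = 41.2, DEPTH = 230, FRAG = 7)
  d <- shift_metrics(base, fut)
  expect_equal(d$dRANGE, -40)
  expect_equal(d$dLAT, 1.2)
  expect_equal(d$dDEPTH, 30)
  expect_equal(d$dFRAG, 2)
  # identical ranges: all deltas zero
  d0 <- shift_metrics(base, dplyr::mutate(base, scenario = "f"))
  expect_true(all(abs(c(d0$dRANGE, d0$dLAT, d0$dDEPTH, d0$dFRAG)) < 1e-12))
  # empty future: extinction with dRANGE exactly -100
  ext <- shift_metrics(base, dplyr::mutate(fut, n_cells = 0L, RANGE = 0))
  expect_true(ext$extinct)
  expect_equal(ext$dRANGE, -100)
  expect_true(is.na(ext$dLAT))
  expect_error(shift_metrics(dplyr::mutate(base, n_cells = 0L), fut), "empty baseline")
  # scale-free: doubling cell areas leaves dRANGE unchanged
  d2 <- shift_metrics(dplyr::mutate(base, RANGE = 400),
                      dplyr::mutate(fut, RANGE = 240))
  expect_equal(d2$dRANGE, -40)
})

test_that("EIV profiles are baseline medians at occurrence cells", {
  w <- toy_stack(10, 10, layers = list(T_median = rep(c(14, 15, 18, 20), 25)))
  occ <- tibble::tibble(species_id = "s", cell = w$cell[1:3])  # T 14, 15, 18
  e <- eiv_profile(occ, w, "T_median", frag = 2.5)
  expect_equal(e$EIV_T_median, 15)
  expect_equal(e$EIV_FRAG, 2.5)
  expect_equal(e$EIV_DEPTH, median(w$depth[1:3]))
  single <- eiv_profile(occ[1, ], w, "T_median")
  expect_equal(single$EIV_T_median, 14)
  expect_equal(single$EIV_LAT, w$lat[1])
  # sort-oracle on random draws
  set.seed(41)
  for (i in 1:10) {
    idx <- sample(nrow(w), 7)
    ei <- eiv_profile(tibble::tibble(species_id = "x", cell = w$cell[idx]), w, "T_median")
    v <- sort(w$T_median[idx])
    expect_equal(ei$EIV_T_median, v[4])
  }
})

test_that("the EIV screen recovers monotone links and rejects noise", {
  set.seed(42)
  n <- 100
  shift <- tibble::tibble(species_id = paste0("s", 1:n), scenario = "f",
                          dLAT = 1:n + 0, dRANGE = rnorm(n))
  eiv <- tibble::tibble(species_id = paste0("s", 1:n),
                        EIV_T_median = (1:n)^1.5,     # monotone in dLAT
                        EIV_DEPTH = rnorm(n))
  scr <- eiv_correlation_screen(shift, eiv)
  r1 <- scr[scr$metric == "dLAT" & scr$eiv == "EIV_T_median", ]
  expect_equal(r1$rho, 1)
  expect_equal(r1$stars, "***")
  # independent columns: |rho| < 0.3 and no extreme significance
  r2 <- scr[scr$metric == "dRANGE" & scr$eiv == "EIV_DEPTH", ]
  expect_lt(abs(r2$rho), 0.3)
  expect_gt(r2$p_value, 0.001)
  # brute-force rank formula oracle on 20 species, no ties
  x <- rnorm(20); y <- rnorm(20)
  s2 <- eiv_correlation_screen(
    tibble::tibble(species_id = 1:20, scenario = "f", dLAT = x),
    tibble::tibble(species_id = 1:20, EIV_T_median = y))
  rho_brute <- 1 - 6 * sum((rank(x) - rank(y))^2) / (20 * (20^2 - 1))
  expect_equal(s2$rho[1], rho_brute, tolerance = 1e-12)
  # constant column flagged undefined
  s3 <- eiv_correlation_screen(
    tibble::tibble(species_id = 1:10, scenario = "f", dLAT = rnorm(10)),
    tibble::tibble(species_id = 1:10, EIV_T_median = rep(1, 10)))
  expect_true(is.na(s3$rho[1]))
})

test_that("driver binning conserves species counts", {
  imp <- dplyr::bind_rows(
    tibble::tibble(species_id = paste0("s", 1:6), predictor = "T_median", rank = 1),
    tibble::tibble(species_id = paste0("s", 1:6), predictor = "SAND", rank = 2))
  imp$predictor[imp$species_id == "s6" & imp$rank == 1] <- "SAND"
  shift <- tibble::tibble(species_id = paste0("s", 1:7), scenario = "f",
                          dRANGE = c(-60, -20, -5, 5, 20, 60, 1))
  db <- driver_binning(imp, shift)
  expect_equal(sum(db$n), 6L)  # s7 has no importance record
  expect_equal(attr(db, "n_missing_importance"), 1L)
  expect_setequal(unique(db$driver), c("T_median", "SAND"))
  all_t <- driver_binning(dplyr::filter(imp, predictor == "T_median", rank == 1),
                          shift)
  expect_true(all(all_t$driver == "T_median"))
})
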