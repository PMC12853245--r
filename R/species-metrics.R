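#' Baseline distributional metrics of a binary range
#'
#' RANGE is the summed cell area (km^2; cells are equal-area on the planar
#' grid), LAT the area-weighted mean latitude of presence cells (degrees,
#' or grid-y units northward in synthetic mode) and DEPTH the area-weighted
#' mean depth (m). An empty range yields missing metrics and an extinction
#' flag.
#'
#' @param range a binary range ([binarize_map()] / [depth_crop()]).
#' @param stack the stack supplying latitude and depth per cell.
#' @return one-row tibble `species_id`, `scenario`, `n_cells`, `RANGE`,
#'   `LAT`, `DEPTH`, `extinct`.
#' @export
range_metrics <- function(range, stack) {
  area <- attr(stack, "cell_km")^2
  idx <- match(range$cell, stack$cell)
  idx <- idx[!is.na(idx)]
  tibble(
    species_id = attr(range, "species_id") %||% NA_character_,
    scenario = attr(range, "scenario") %||% NA_character_,
    n_cells = length(idx),
    RANGE = length(idx) * area,
    LAT = if (length(idx)) mean(stack$lat[idx]) else NA_real_,
    DEPTH = if (length(idx)) mean(stack$depth[idx]) else NA_real_,
    extinct = length(idx) == 0)
}

# Connected components of presence cells (rook or queen adjacency) on the
# grid; returns integer labels aligned with `cells` rows.
clump_labels <- function(rows, cols, dims, connectivity = 4) {
  n <- length(rows)
  if (!n) return(integer())
  idx <- matrix(0L, dims[1], dims[2])
  idx[cbind(rows, cols)] <- seq_len(n)
  labels <- integer(n)
  nb <- if (connectivity == 4) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
        else cbind(rep(c(-1, 0, 1), 3), rep(c(-1, 0, 1), each = 3))[-5, ]
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i]) next
    cur <- cur + 1L
    queue <- i; labels[i] <- cur
    while (length(queue)) {
      j <- queue[length(queue)]; queue <- queue[-length(queue)]
      rr <- rows[j] + nb[, 1]; cc <- cols[j] + nb[, 2]
      ok <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
      nbr <- idx[cbind(rr[ok], cc[ok])]
      nbr <- nbr[nbr > 0]
      nbr <- nbr[labels[nbr] == 0]
      labels[nbr] <- cur
      queue <- c(queue, nbr)
    }
  }
  labels
}

# Multi-source BFS step distances over sea cells from a set of source
# cells; land impassable, rook moves, unit cost per step.
bfs_distances <- function(source_cells, sea_mask) {
  d <- dim(sea_mask)
  dist <- matrix(NA_integer_, d[1], d[2])
  dist[source_cells] <- 0L
  frontier <- source_cells
  step <- 0L
  while (length(frontier)) {
    step <- step + 1L
    rr <- (frontier - 1L) %% d[1] + 1L
    cc <- (frontier - 1L) %/% d[1] + 1L
    cand <- c(frontier[rr > 1] - 1L, frontier[rr < d[1]] + 1L,
              frontier[cc > 1] - d[1], frontier[cc < d[2]] + d[1])
    cand <- unique(cand)
    cand <- cand[sea_mask[cand] & is.na(dist[cand])]
    dist[cand] <- step
    frontier <- cand
  }
  dist
}

#' Range fragmentation: mean inter-clump sea distance
#'
#' Clumps are connected components of presence cells (rook adjacency by
#' default). The distance between two clumps is the shortest path through
#' sea cells from any cell of one to any cell of the other, counted
#' edge-to-edge in cell steps (adjacent clumps are at distance 0) and
#' scaled to km; land is impassable. FRAG is the mean over all unordered
#' clump pairs; a single clump or an empty range has FRAG 0. Pairs with no
#' sea path are excluded from the mean and counted.
#'
#' @param range a binary range.
#' @param stack the stack (defines the sea mask and cell size).
#' @param connectivity 4 (rook, default) or 8 (queen) for clump adjacency.
#' @return one-row tibble `species_id`, `scenario`, `n_clumps`, `FRAG`
#'   (km), `unreachable_pairs`.
#' @export
fragmentation <- function(range, stack, connectivity = 4) {
  d <- stack_dims(stack)
  ck <- attr(stack, "cell_km")
  lab <- clump_labels(range$row, range$col, d, connectivity)
  k <- if (length(lab)) max(lab) else 0L
  if (k <= 1) {
    return(tibble(species_id = attr(range, "species_id") %||% NA_character_,
                  scenario = attr(range, "scenario") %||% NA_character_,
                  n_clumps = k, FRAG = 0, unreachable_pairs = 0L))
  }
  sea <- matrix(FALSE, d[1], d[2])
  sea[cbind(stack$row, stack$col)] <- TRUE
  # column-major linear indices for the mask
  lin <- (range$col - 1L) * d[1] + range$row
  dists <- matrix(NA_real_, k, k)
  for (a in seq_len(k - 1)) {
    dm <- bfs_distances(lin[lab == a], sea)
    for (b in seq((a + 1), k)) {
      db <- dm[lin[lab == b]]
      dists[a, b] <- if (all(is.na(db))) NA_real_ else max(min(db, na.rm = TRUE) - 1L, 0L)
    }
  }
  pair <- dists[upper.tri(dists)]
  unreach <- sum(is.na(pair))
  if (unreach)
    warn(sprintf("fragmentation: %d clump pair(s) with no sea path excluded", unreach))
  frag <- if (all(is.na(pair))) 0 else mean(pair, na.rm = TRUE) * ck
  tibble(species_id = attr(range, "species_id") %||% NA_character_,
         scenario = attr(range, "scenario") %||% NA_character_,
         n_clumps = k, FRAG = frag, unreachable_pairs = unreach)
}

#' Change in distributional metrics between baseline and future
#'
#' Relative range change `ΔRANGE = 100 (RANGE_f - RANGE_b) / RANGE_b` (%),
#' and absolute changes `ΔLAT`, `ΔDEPTH`, `ΔFRAG`. A species whose future
#' range is empty goes extinct: `ΔRANGE = -100`, other deltas undefined.
#'
#' @param baseline,future one-row metric tibbles
#'   ([range_metrics()] joined with [fragmentation()]'s `FRAG` column when
#'   fragmentation deltas are wanted).
#' @return one-row tibble `species_id`, `scenario`, `dRANGE`, `dLAT`,
#'   `dDEPTH`, `dFRAG`, `extinct`.
#' @export
shift_metrics <- function(baseline, future) {
  if (baseline$n_cells == 0) abort("shift_metrics: empty baseline range")
  has_frag <- all(c("FRAG") %in% names(baseline)) && "FRAG" %in% names(future)
  if (future$n_cells == 0) {
    return(tibble(species_id = future$species_id, scenario = future$scenario,
                  dRANGE = -100, dLAT = NA_real_, dDEPTH = NA_real_,
                  dFRAG = NA_real_, extinct = TRUE))
  }
  tibble(species_id = future$species_id, scenario = future$scenario,
         dRANGE = 100 * (future$RANGE - baseline$RANGE) / baseline$RANGE,
         dLAT = future$LAT - baseline$LAT,
         dDEPTH = future$DEPTH - baseline$DEPTH,
         dFRAG = if (has_frag) future$FRAG - baseline$FRAG else NA_real_,
         extinct = FALSE)
}

#' Ecological indicator values of a species
#'
#' EIVs summarise a species' realized niche as the median baseline
#' condition at its occurrence cells: one EIV per retained predictor plus
#' median depth, median latitude, and the species' baseline fragmentation.
#'
#' @param occurrences the species' occurrence cells (`cell`).
#' @param stack the baseline stack.
#' @param predictors predictors to profile.
#' @param frag the species' baseline FRAG (km), stored as `EIV_FRAG`.
#' @return one-row tibble `species_id`, `EIV_<predictor>` ...,
#'   `EIV_DEPTH`, `EIV_LAT`, `EIV_FRAG`.
#' @export
eiv_profile <- function(occurrences, stack, predictors = stack_predictors(stack),
                        frag = NA_real_) {
  if (nrow(occurrences) == 0) abort("eiv_profile: no occurrences")
  idx <- match(unique(occurrences$cell), stack$cell)
  idx <- idx[!is.na(idx)]
  vals <- lapply(predictors, function(p) median(stack[[p]][idx]))
  names(vals) <- paste0("EIV_", predictors)
  bind_cols(tibble(species_id = occurrences$species_id[1] %||% NA_character_),
            as_tibble(vals),
            tibble(EIV_DEPTH = median(stack$depth[idx]),
                   EIV_LAT = median(stack$lat[idx]), EIV_FRAG = frag))
}

#' Spearman screen of shift metrics against EIVs
#'
#' Rank-correlates every change metric with every EIV across species,
#' pairwise-complete, with two-sided p-values and significance stars
#' (`.` < 0.1, `*` < 0.05, `**` < 0.01, `***` < 0.001). Constant columns
#' yield undefined correlations (NA).
#'
#' @param shift_table species-level tibble with `species_id` and change
#'   metric columns (`dRANGE`, `dLAT`, `dDEPTH`, `dFRAG`).
#' @param eiv_table species-level tibble with `species_id` and `EIV_*`
#'   columns.
#' @param metrics,eivs column subsets to screen (defaults: all present).
#' @return tibble `metric`, `eiv`, `rho`, `p_value`, `n`, `stars`.
#' @export
eiv_correlation_screen <- function(shift_table, eiv_table,
                                   metrics = intersect(c("dRANGE", "dLAT", "dDEPTH", "dFRAG"),
                                                       names(shift_table)),
                                   eivs = grep("^EIV_", names(eiv_table), value = TRUE)) {
  joined <- inner_join(shift_table, eiv_table, by = "species_id")
  if (nrow(joined) < 5) abort("eiv_correlation_screen: need >= 5 species")
  tidyr::expand_grid(metric = metrics, eiv = eivs) |>
    purrr::pmap(function(metric, eiv) {
      x <- joined[[metric]]; y <- joined[[eiv]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 5 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
        return(tibble(metric = metric, eiv = eiv, rho = NA_real_,
                      p_value = NA_real_, n = sum(ok), stars = ""))
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      tibble(metric = metric, eiv = eiv, rho = unname(ct$estimate),
             p_value = ct$p.value, n = sum(ok), stars = star_code(ct$p.value))
    }) |> bind_rows()
}

#' Group species by leading driver and bin their metric changes
#'
#' Labels each species with its first-ranked permutation-importance
#' predictor and cross-tabulates drivers against binned metric change —
#' the data behind stacked driver bars.
#'
#' @param importance_table tibble `species_id`, `predictor`, `rank`
#'   (rank 1 rows are used).
#' @param shift_table tibble `species_id`, `scenario`, metric columns.
#' @param metric which change metric to bin.
#' @param breaks bin edges passed to [base::cut()].
#' @return tibble `scenario`, `driver`, `bin`, `n`; species without an
#'   importance record are excluded and counted in the
#'   `n_missing_importance` attribute.
#' @export
driver_binning <- function(importance_table, shift_table, metric = "dRANGE",
                           breaks = c(-Inf, -50, -10, 0, 10, 50, Inf)) {
  top <- filter(importance_table, .data$rank == 1) |>
    select("species_id", driver = "predictor")
  joined <- inner_join(shift_table, top, by = "species_id")
  n_missing <- length(setdiff(unique(shift_table$species_id), top$species_id))
  out <- joined |>
    mutate(bin = cut(.data[[metric]], breaks = breaks)) |>
    count(.data$scenario, .data$driver, .data$bin, name = "n")
  attr(out, "n_missing_importance") <- n_missing
  out
}
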