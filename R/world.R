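#' Generate a synthetic ocean world
#'
#' Builds a planar gridded "sea" with land blobs, a shelf-to-slope depth
#' field, and the seven baseline predictor layers used throughout the
#' pipeline (`T_median`, `T_min`, `O2_median`, `CHL_median`, `SAL_median`,
#' `Vm_median`, `SAND`). The construction imposes the gradients the real
#' system shows at basin scale:
#'
#' * temperature decreases northward (row 1 is north) and with depth;
#' * oxygen is negatively correlated with temperature;
#' * chlorophyll is coastally enhanced; all fields are spatially
#'   autocorrelated (Gaussian-smoothed noise).
#'
#' Everything is a pure function of `seed`: the same call yields a
#' bit-identical world.
#'
#' @param rows,cols grid dimensions (each at least 20).
#' @param seed integer RNG seed.
#' @param cell_km cell edge length (km); the synthetic grid is planar with
#'   equal-area cells.
#' @param land_quantile fraction of the grid turned into land blobs.
#' @return an [env_stack()] with provenance `"baseline"` and an extra
#'   `dist_land` column (distance to the nearest land cell, km) used for
#'   coastal sampling bias.
#' @export
generate_world <- function(rows = 60, cols = 100, seed = 1, cell_km = 1,
                           land_quantile = 0.15) {
  if (rows < 20 || cols < 20) abort("generate_world: rows and cols must be >= 20")
  d <- c(as.integer(rows), as.integer(cols))
  with_seed(derive_seed(seed, "world"), {
    lat_frac <- matrix((rows - seq_len(rows) + 0.5) / rows, rows, cols)
    # the basin narrows northward: land is likelier at high latitude, so a
    # poleward-shifting niche meets less sea
    elev <- smooth_field(d, range = 6) + 1.6 * (lat_frac - 0.5)
    land <- elev > quantile(elev, 1 - land_quantile)
    dist_land <- distance_transform(land) * cell_km
    depth <- clamp(800 * (1 - exp(-dist_land / (10 * cell_km))) *
                     (0.75 + 0.5 * plogis(smooth_field(d, range = 8))), 2, 800)
    T_med <- 26 - 13.5 * lat_frac - 1.2 * depth / 800 + 0.5 * smooth_field(d, range = 4)
    T_min <- T_med - (1.2 + plogis(smooth_field(d, range = 5)))
    O2 <- clamp(330 - 6 * T_med + 25 * smooth_field(d, range = 4), 120, Inf)
    CHL <- clamp(2.5 * exp(-dist_land / (8 * cell_km)) + 0.3 +
                   0.35 * smooth_field(d, range = 4), 0.05, Inf)
    SAL <- 36 + 1.5 * matrix(rep((seq_len(cols) - 0.5) / cols, each = rows), rows, cols) +
      0.5 * smooth_field(d, range = 5)
    Vm <- clamp(0.18 + 0.1 * smooth_field(d, range = 4), 0.01, Inf)
    SAND <- plogis(1.2 * smooth_field(d, range = 5))
    sea <- which(!land, arr.ind = TRUE)
    cells <- tibble(
      row = as.integer(sea[, 1]), col = as.integer(sea[, 2]),
      depth = depth[sea], dist_land = dist_land[sea],
      T_median = T_med[sea], T_min = T_min[sea], O2_median = O2[sea],
      CHL_median = CHL[sea], SAL_median = SAL[sea], Vm_median = Vm[sea],
      SAND = SAND[sea])
    env_stack(cells, dims = d,
              predictors = c("T_median", "T_min", "O2_median", "CHL_median",
                             "SAL_median", "Vm_median", "SAND"),
              cell_km = cell_km, provenance = "baseline")
  })
}

# Chebyshev distance (in cells) to the nearest TRUE cell, by iterative
# dilation; exact for the smooth coastal-decay use it serves.
distance_transform <- function(mask) {
  d <- dim(mask)
  dist <- matrix(Inf, d[1], d[2])
  dist[mask] <- 0
  frontier <- mask
  step <- 0
  while (any(is.infinite(dist)) && step < sum(d)) {
    step <- step + 1
    grown <- frontier
    grown[-1, ] <- grown[-1, ] | frontier[-d[1], ]
    grown[-d[1], ] <- grown[-d[1], ] | frontier[-1, ]
    grown[, -1] <- grown[, -1] | frontier[, -d[2]]
    grown[, -d[2]] <- grown[, -d[2]] | frontier[, -1]
    # diagonals for Chebyshev growth
    grown[-1, -1] <- grown[-1, -1] | frontier[-d[1], -d[2]]
    grown[-1, -d[2]] <- grown[-1, -d[2]] | frontier[-d[1], -1]
    grown[-d[1], -1] <- grown[-d[1], -1] | frontier[-1, -d[2]]
    grown[-d[1], -d[2]] <- grown[-d[1], -d[2]] | frontier[-1, -1]
    newly <- grown & is.infinite(dist)
    dist[newly] <- step
    frontier <- grown
  }
  dist[is.infinite(dist)] <- sum(d)  # no land anywhere
  dist
}

#' Multiplicative scenario anomalies for the synthetic world
#'
#' Emulates scenario forcing as per-predictor multiplicative anomaly grids:
#' warming (temperature factors > 1, stronger in the south so isotherms
#' migrate north) and mild deoxygenation, with all other predictors left
#' unchanged. Factor magnitudes scale with scenario severity and time
#' window.
#'
#' @param world baseline [env_stack()] from [generate_world()].
#' @param scenario `"rcp45"` or `"rcp85"`.
#' @param window `"near"` or `"far"`.
#' @return a `scenario_anomaly`: tibble `cell` plus one anomaly column per
#'   predictor (all strictly positive), with `scenario`/`window` attributes.
#' @export
make_anomaly <- function(world, scenario = c("rcp45", "rcp85"),
                         window = c("near", "far")) {
  scenario <- match.arg(scenario); window <- match.arg(window)
  w <- c(rcp45_near = 0.025, rcp45_far = 0.045,
         rcp85_near = 0.040, rcp85_far = 0.080)[[paste(scenario, window, sep = "_")]]
  d <- stack_dims(world)
  lat_frac <- (world$lat / attr(world, "cell_km")) / d[1]
  t_fac <- 1 + w * (1.3 - 0.6 * lat_frac)   # stronger warming in the south
  o2_fac <- 1 - 0.5 * w * (1.2 - 0.4 * lat_frac)
  out <- tibble(cell = world$cell,
                T_median = t_fac, T_min = t_fac, O2_median = o2_fac,
                CHL_median = 1, SAL_median = 1, Vm_median = 1, SAND = 1)
  structure(out, scenario = scenario, window = window,
            dims = d, class = c("scenario_anomaly", class(tibble())))
}

#' Force a baseline stack with a multiplicative anomaly
#'
#' Future conditions are the baseline value multiplied by the climatic
#' anomaly, per predictor per cell. Depth, mask and geometry are unchanged.
#'
#' @param world baseline [env_stack()].
#' @param anomaly a `scenario_anomaly` (from [make_anomaly()]) or any tibble
#'   with a `cell` column and one positive multiplier column per predictor.
#' @return an [env_stack()] tagged with the anomaly's scenario/window.
#' @export
apply_anomaly <- function(world, anomaly) {
  if (!is.null(attr(anomaly, "dims")) &&
      !identical(attr(anomaly, "dims"), stack_dims(world)))
    abort("apply_anomaly: grid shapes differ")
  preds <- stack_predictors(world)
  miss <- setdiff(preds, names(anomaly))
  if (length(miss))
    abort(paste0("apply_anomaly: anomaly missing predictor(s): ",
                 paste(miss, collapse = ", ")))
  fac <- anomaly[match(world$cell, anomaly$cell), preds]
  if (anyNA(fac)) abort("apply_anomaly: anomaly does not cover all sea cells")
  if (any(as.matrix(fac) <= 0)) abort("apply_anomaly: anomaly factors must be > 0")
  cells <- as_tibble(world)
  for (p in preds) cells[[p]] <- cells[[p]] * fac[[p]]
  tag <- paste(attr(anomaly, "scenario") %||% "scenario",
               attr(anomaly, "window") %||% "", sep = "_")
  rebuild_stack(cells, world, provenance = sub("_$", "", tag))
}
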