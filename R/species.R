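#' Virtual species with analytically known niches
#'
#' A virtual species is defined by per-predictor response curves whose
#' product gives a true habitat-suitability surface in \[0, 1\]. Because the
#' truth is analytic, every downstream stage (model fitting, projection,
#' shift metrics, community change) can be checked against exact
#' ground-truth quantities.
#'
#' The default species responds to temperature only: a Gaussian response on
#' `T_median` centred at `thermal_optimum` with standard deviation
#' `breadth`, flat (value 1) on every other predictor. Additional curves
#' can be supplied via `responses`: a named list of
#' `list(type = "gaussian", opt =, sd =)` or
#' `list(type = "logistic", mid =, slope =)` entries keyed by predictor.
#'
#' @param world baseline [env_stack()].
#' @param id species identifier.
#' @param thermal_optimum optimum temperature (degrees C) of the default
#'   Gaussian response on `T_median`.
#' @param breadth its standard deviation (> 0).
#' @param responses optional response list overriding the default.
#' @return a `virtual_species` object: list with `id`, `responses`,
#'   `thermal_optimum`, the true baseline `suitability` tibble
#'   (`cell`, `row`, `col`, `suitability`) and an `out_of_range` flag set
#'   when the optimum lies outside the world's temperature range.
#' @export
make_virtual_species <- function(world, id = "sp1", thermal_optimum = 18,
                                 breadth = 1.5, responses = NULL) {
  if (!is.null(breadth) && breadth <= 0) abort("make_virtual_species: breadth must be > 0")
  default_thermal <- is.null(responses)
  if (default_thermal)
    responses <- list(T_median = list(type = "gaussian", opt = thermal_optimum,
                                      sd = breadth))
  bad <- setdiff(names(responses), stack_predictors(world))
  if (length(bad))
    abort(paste0("make_virtual_species: unknown predictor(s): ", paste(bad, collapse = ", ")))
  t_rng <- range(world$T_median)
  oor <- default_thermal && !is.null(thermal_optimum) &&
    (thermal_optimum < t_rng[1] || thermal_optimum > t_rng[2])
  if (oor) warn(sprintf("species %s: thermal optimum %.1f outside world range [%.1f, %.1f]",
                        id, thermal_optimum, t_rng[1], t_rng[2]))
  sp <- structure(
    list(id = id, responses = responses, thermal_optimum = thermal_optimum,
         out_of_range = oor),
    class = "virtual_species")
  sp$suitability <- true_suitability(sp, world)
  sp
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> %s: responses on %s; thermal optimum %s\n",
              x$id, paste(names(x$responses), collapse = ", "),
              format(x$thermal_optimum)))
  invisible(x)
}

response_value <- function(resp, x) {
  switch(resp$type,
         gaussian = exp(-(x - resp$opt)^2 / (2 * resp$sd^2)),
         logistic = plogis(resp$slope * (x - resp$mid)),
         flat = rep(1, length(x)),
         abort(paste0("unknown response type: ", resp$type)))
}

#' True suitability of a virtual species under any stack
#'
#' Evaluates the species' response-curve product on the given conditions —
#' the analytic ground truth against which fitted projections are compared.
#' Land cells (absent from the stack) have suitability 0 by construction;
#' [suitability_matrix()] materialises that convention on the full grid.
#'
#' @param species a `virtual_species`.
#' @param stack an [env_stack()] (baseline or scenario-forced).
#' @return tibble `cell`, `row`, `col`, `suitability`.
#' @export
true_suitability <- function(species, stack) {
  s <- rep(1, nrow(stack))
  for (p in names(species$responses))
    s <- s * response_value(species$responses[[p]], stack[[p]])
  tibble(cell = stack$cell, row = stack$row, col = stack$col, suitability = s)
}

#' @rdname true_suitability
#' @export
suitability_matrix <- function(species, stack) {
  d <- stack_dims(stack)
  m <- matrix(0, d[1], d[2])  # land = 0
  su <- true_suitability(species, stack)
  m[cbind(su$row, su$col)] <- su$suitability
  m
}

#' Ground-truth range metrics from true suitability
#'
#' Thresholds the true suitability at `threshold` and computes the same
#' distributional metrics the fitted pipeline reports — occupied range area,
#' latitudinal centroid and mean depth — directly from the truth,
#' independent of any model. Used as the recovery oracle for the fitted
#' pipeline.
#'
#' @inheritParams true_suitability
#' @param threshold suitability cut defining the true occupied range.
#' @return one-row tibble `species_id`, `n_cells`, `RANGE`, `LAT`, `DEPTH`.
#' @export
true_range_metrics <- function(species, stack, threshold = 0.5) {
  su <- true_suitability(species, stack)
  occ <- su$suitability >= threshold
  area <- attr(stack, "cell_km")^2
  tibble(species_id = species$id, n_cells = sum(occ),
         RANGE = sum(occ) * area,
         LAT = if (any(occ)) mean(stack$lat[occ]) else NA_real_,
         DEPTH = if (any(occ)) mean(stack$depth[occ]) else NA_real_)
}

#' Coastal sampling-effort bias field
#'
#' Presence-only archives oversample near the coast. The emulated effort
#' field decays exponentially with distance to land.
#'
#' @param world [env_stack()] with a `dist_land` column.
#' @param decay_km e-folding distance of sampling effort (km).
#' @return tibble `cell`, `bias` (positive weights).
#' @export
coastal_bias <- function(world, decay_km = 5) {
  if (!"dist_land" %in% names(world)) abort("coastal_bias: world lacks dist_land")
  tibble(cell = world$cell, bias = exp(-world$dist_land / decay_km))
}

#' Sample biased presence-only occurrences of a virtual species
#'
#' Draws `n` presence cells without replacement from the world's sea cells
#' with probability proportional to true suitability times the sampling
#' bias, yielding at most one record per cell (the thinned-data convention
#' downstream stages expect). Deterministic for a fixed seed.
#'
#' @param species a `virtual_species`.
#' @param world baseline [env_stack()].
#' @param n number of presence cells (>= 1).
#' @param bias tibble `cell`, `bias` (e.g. [coastal_bias()]); `NULL` for
#'   uniform effort.
#' @param seed integer seed.
#' @return tibble `species_id`, `cell`, `row`, `col`.
#' @export
sample_occurrences <- function(species, world, n, bias = NULL, seed = 1) {
  if (n < 1) abort("sample_occurrences: n must be >= 1")
  su <- species$suitability
  w <- su$suitability
  if (!is.null(bias)) {
    b <- bias$bias[match(su$cell, bias$cell)]
    if (anyNA(b) || any(b < 0)) abort("sample_occurrences: bias must cover all sea cells, nonnegative")
    w <- w * b
  }
  pos <- which(w > 0)
  if (!length(pos)) abort("sample_occurrences: no cell with positive weight")
  if (length(pos) < n) {
    warn(sprintf("sample_occurrences: only %d cells with positive weight (< n = %d); returning all",
                 length(pos), n))
    idx <- pos
  } else {
    idx <- with_seed(derive_seed(seed, paste0("occ_", species$id)),
                     sample(pos, n, replace = FALSE, prob = w[pos]))
  }
  tibble(species_id = species$id, cell = su$cell[idx],
         row = su$row[idx], col = su$col[idx]) |> arrange(.data$cell)
}
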