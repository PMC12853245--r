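#' Project an ensemble onto a stack
#'
#' Cellwise mean suitability of the retained members over a baseline or
#' scenario-forced stack.
#'
#' @param ensemble a usable `sdm_ensemble`.
#' @param stack an [env_stack()] providing every model predictor.
#' @return a suitability map: tibble `cell`, `row`, `col`, `suitability`
#'   with attributes `species_id`, `scenario` (the stack's provenance) and
#'   `threshold` (the ensemble's stored binarization threshold).
#' @export
project_ensemble <- function(ensemble, stack) {
  miss <- setdiff(ensemble$predictors, names(stack))
  if (length(miss))
    abort(paste0("project_ensemble: stack missing predictor(s): ",
                 paste(miss, collapse = ", ")))
  if (!length(ensemble$retained))
    abort(sprintf("project_ensemble: species %s has no retained members", ensemble$species_id))
  cached <- ensemble$baseline_prediction
  suit <- if (!is.null(cached) &&
              identical(attr(stack, "provenance"), ensemble$baseline_provenance) &&
              identical(cached$cell, stack$cell))
    cached$suitability
  else ensemble_predict(ensemble, stack)
  structure(tibble(cell = stack$cell, row = stack$row, col = stack$col,
                   suitability = suit),
            species_id = ensemble$species_id,
            scenario = attr(stack, "provenance"),
            threshold = ensemble$threshold,
            dims = stack_dims(stack),
            class = c("suitability_map", class(tibble())))
}

#' Binarize a suitability map
#'
#' Thresholds continuous suitability into a presence/absence range. The
#' default threshold is the one maximising TSS on the species' baseline
#' evaluation data, fixed once per species and reused for every scenario
#' so ranges are comparable across time.
#'
#' @param map a suitability map from [project_ensemble()].
#' @param threshold numeric threshold; defaults to the map's stored
#'   (baseline-derived) max-TSS threshold.
#' @return a binary range: tibble of presence cells (`cell`, `row`, `col`)
#'   with attributes `species_id`, `scenario`, `threshold`, `dims`.
#' @export
binarize_map <- function(map, threshold = attr(map, "threshold")) {
  if (is.null(threshold) || is.na(threshold))
    abort("binarize_map: no threshold available (ensemble lacks evaluation data)")
  out <- filter(as_tibble(map), .data$suitability >= threshold) |>
    select("cell", "row", "col")
  structure(out, species_id = attr(map, "species_id"),
            scenario = attr(map, "scenario"), threshold = threshold,
            dims = attr(map, "dims"),
            class = c("binary_range", class(tibble())))
}

#' Crop a binary range to the species' plausible depth window
#'
#' Future ranges are constrained to depths the species could plausibly
#' reach: 30% shallower than the 5th percentile and 30% deeper than the
#' 95th percentile of its baseline depths. Cells outside
#' `[0.7 * p5, 1.3 * p95]` are removed; an empty result is allowed and
#' feeds the extinction accounting.
#'
#' @param range a binary range ([binarize_map()]).
#' @param stack the stack supplying cell depths.
#' @param baseline_occurrences baseline occurrence cells (`cell`); their
#'   depths define the percentiles when `depths` is not given.
#' @param depths optional numeric vector of baseline depths (m), e.g. from
#'   the predicted baseline range instead of occurrences.
#' @return the cropped binary range with a `depth_window` attribute
#'   `c(lower, upper)` in metres.
#' @export
depth_crop <- function(range, stack, baseline_occurrences = NULL, depths = NULL) {
  if (is.null(depths)) {
    if (is.null(baseline_occurrences) || nrow(baseline_occurrences) == 0)
      abort("depth_crop: baseline occurrence depths required")
    depths <- stack$depth[match(unique(baseline_occurrences$cell), stack$cell)]
    depths <- depths[!is.na(depths)]
  }
  if (!length(depths)) abort("depth_crop: no baseline depths")
  q <- quantile(depths, c(0.05, 0.95), names = FALSE)
  window <- c(0.7 * q[1], 1.3 * q[2])
  cell_depth <- stack$depth[match(range$cell, stack$cell)]
  keep <- !is.na(cell_depth) & cell_depth >= window[1] & cell_depth <= window[2]
  out <- range[keep, ]
  for (a in c("species_id", "scenario", "threshold", "dims"))
    attr(out, a) <- attr(range, a)
  attr(out, "depth_window") <- window
  class(out) <- class(range)
  out
}

#' Multivariate environmental similarity surface
#'
#' Per cell and predictor, similarity to the training sample: negative when
#' the cell's value lies outside the training min-max (scaled shortfall
#' times 100), otherwise a 0-100 score from the training empirical
#' percentile f (percent of training values below the cell value): `2f` if
#' `f <= 50`, else `2(100 - f)`. The cell's MESS is the minimum across
#' predictors; negative values flag novel (extrapolated) conditions.
#' A constant training predictor only distinguishes inside (0) from
#' outside (negative) its point range.
#'
#' @param stack the projection stack.
#' @param training tibble of training rows carrying the predictor columns
#'   (e.g. an ensemble's pooled tables).
#' @param predictors predictor names (default: all the training table and
#'   stack share).
#' @return tibble `cell`, `row`, `col`, `mess`, `mess_predictor` (the
#'   minimising predictor).
#' @export
mess_grid <- function(stack, training,
                      predictors = intersect(stack_predictors(stack), names(training))) {
  if (!length(predictors)) abort("mess_grid: no shared predictors")
  sims <- vapply(predictors, function(p) {
    tr <- training[[p]]
    tr <- tr[!is.na(tr)]
    if (!length(tr)) abort(sprintf("mess_grid: empty training sample for %s", p))
    v <- stack[[p]]
    mn <- min(tr); mx <- max(tr); rng <- mx - mn
    if (rng == 0) {
      out <- ifelse(v == mn, 0, -100 * abs(v - mn) / max(abs(mn), 1))
      return(out)
    }
    f <- 100 * findInterval(v, sort(tr), left.open = TRUE) / length(tr)
    ifelse(v < mn, 100 * (v - mn) / rng,
           ifelse(v > mx, 100 * (mx - v) / rng,
                  ifelse(f <= 50, 2 * f, 2 * (100 - f))))
  }, numeric(nrow(stack)))
  sims <- matrix(sims, nrow = nrow(stack),
                 dimnames = list(NULL, predictors))
  mi <- max.col(-sims, ties.method = "first")
  tibble(cell = stack$cell, row = stack$row, col = stack$col,
         mess = sims[cbind(seq_len(nrow(sims)), mi)],
         mess_predictor = predictors[mi])
}
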