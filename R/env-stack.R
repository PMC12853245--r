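#' Environmental predictor stacks
#'
#' An `env_stack` is a tidy per-cell table of environmental conditions on a
#' regular planar grid: one row per sea cell inside the modelled depth
#' window, with columns `cell`, `row`, `col`, `lat`, `depth` plus one column
#' per named predictor. Grid geometry (row/col counts, cell size in km) and
#' a provenance tag (`"baseline"` or scenario/window labels) travel in
#' attributes so the table pipes through dplyr verbs untouched.
#'
#' Cells absent from the table are land or outside the depth window; the
#' implied land/sea mask is recoverable via [stack_mask()]. Latitude in
#' planar (synthetic) mode is the northward cell-centre coordinate in cell
#' units: row 1 is the northernmost row.
#'
#' @param cells tibble with at least `row`, `col`, `depth` and predictor
#'   columns; one row per sea cell.
#' @param dims integer vector `c(rows, cols)` of the full grid.
#' @param predictors character vector naming the predictor columns.
#' @param cell_km cell edge length in km (planar).
#' @param provenance free-text tag, e.g. `"baseline"` or `"rcp85_far"`.
#' @param max_depth cells deeper than this (m) are excluded from the stack
#'   (and thus from all downstream stages).
#' @return an `env_stack` tibble.
#' @export
env_stack <- function(cells, dims, predictors, cell_km = 1,
                      provenance = "baseline", max_depth = 800) {
  cells <- as_tibble(cells)
  needed <- c("row", "col", "depth", predictors)
  miss <- setdiff(needed, names(cells))
  if (length(miss)) abort(paste0("env_stack: missing columns: ", paste(miss, collapse = ", ")))
  if (any(cells$row < 1 | cells$row > dims[1] | cells$col < 1 | cells$col > dims[2]))
    abort("env_stack: cell indices outside grid dimensions")
  cells <- filter(cells, .data$depth <= max_depth)
  cells$cell <- cell_id(cells$row, cells$col, dims)
  if (anyDuplicated(cells$cell)) abort("env_stack: duplicate cells")
  if (!"lat" %in% names(cells))
    cells$lat <- (dims[1] - cells$row + 0.5) * cell_km
  cells <- select(cells, "cell", "row", "col", "lat", "depth", dplyr::all_of(predictors),
                  dplyr::any_of("dist_land"))
  structure(
    cells,
    dims = as.integer(dims), cell_km = cell_km,
    predictors = predictors, provenance = provenance,
    class = c("env_stack", class(tibble())))
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d x %d grid (%.3g km cells), %d sea cells, provenance: %s\n",
              stack_dims(x)[1], stack_dims(x)[2], attr(x, "cell_km"),
              nrow(x), attr(x, "provenance")))
  cat("predictors:", paste(stack_predictors(x), collapse = ", "), "\n")
  NextMethod()
}

#' Grid geometry and layer accessors
#'
#' @param stack an [env_stack()].
#' @return `stack_dims()`: integer `c(rows, cols)`; `stack_predictors()`:
#'   character vector; `stack_mask()`: logical matrix (TRUE = sea cell in
#'   the stack); `layer_matrix()`: numeric matrix with `NA` off-stack.
#' @export
stack_dims <- function(stack) attr(stack, "dims")

#' @rdname stack_dims
#' @export
stack_predictors <- function(stack) attr(stack, "predictors")

#' @rdname stack_dims
#' @export
stack_mask <- function(stack) {
  d <- stack_dims(stack)
  m <- matrix(FALSE, d[1], d[2])
  m[cbind(stack$row, stack$col)] <- TRUE
  m
}

#' @rdname stack_dims
#' @param var column name to extract.
#' @export
layer_matrix <- function(stack, var) {
  d <- stack_dims(stack)
  m <- matrix(NA_real_, d[1], d[2])
  m[cbind(stack$row, stack$col)] <- stack[[var]]
  m
}

same_geometry <- function(a, b) {
  identical(stack_dims(a), stack_dims(b)) &&
    isTRUE(all.equal(attr(a, "cell_km"), attr(b, "cell_km")))
}

# rebuild an env_stack from a cells table, copying geometry from `like`
rebuild_stack <- function(cells, like, provenance = attr(like, "provenance"),
                          predictors = stack_predictors(like)) {
  env_stack(cells, dims = stack_dims(like), predictors = predictors,
            cell_km = attr(like, "cell_km"), provenance = provenance)
}

#' Aggregate a monthly series into per-cell temporal statistics
#'
#' Collapses an ordered monthly series to the four per-cell statistics used
#' as candidate predictors: median, minimum, maximum and range
#' (maximum minus minimum).
#'
#' @param series long tibble with columns `cell`, `time`, `value` (one row
#'   per cell per month). Cells with all values missing stay missing.
#' @param min_steps minimum number of time steps required (12 by default:
#'   at least one full year).
#' @return tibble with columns `cell`, `median`, `min`, `max`, `range`.
#' @export
aggregate_monthly <- function(series, min_steps = 12) {
  stopifnot(all(c("cell", "time", "value") %in% names(series)))
  if (length(unique(series$time)) < min_steps)
    abort(sprintf("aggregate_monthly: need >= %d time steps", min_steps))
  series |>
    group_by(.data$cell) |>
    summarise(
      median = if (all(is.na(.data$value))) NA_real_ else median(.data$value, na.rm = TRUE),
      min    = if (all(is.na(.data$value))) NA_real_ else min(.data$value, na.rm = TRUE),
      max    = if (all(is.na(.data$value))) NA_real_ else max(.data$value, na.rm = TRUE),
      .groups = "drop") |>
    mutate(range = .data$max - .data$min)
}

#' Remove a control-run drift from a scenario series
#'
#' Long climate simulations can drift for numerical reasons unrelated to
#' forcing. Per cell, the ordinary-least-squares linear trend of the control
#' series is estimated and subtracted from the scenario series, anchored so
#' the scenario's first time step is unchanged (the correction at
#' `t = min(time)` is zero).
#'
#' @param scenario,control long tibbles (`cell`, `time`, `value`) on the same
#'   cells and time axis.
#' @return a long tibble shaped like `scenario` with the control trend
#'   removed.
#' @export
detrend_with_control <- function(scenario, control) {
  stopifnot(all(c("cell", "time", "value") %in% names(scenario)))
  times <- sort(unique(scenario$time))
  if (length(times) < 3) abort("detrend_with_control: need >= 3 time steps")
  if (!identical(times, sort(unique(control$time))))
    abort("detrend_with_control: scenario and control time axes differ")
  slopes <- control |>
    group_by(.data$cell) |>
    summarise(slope = {
      tt <- .data$time - mean(.data$time)
      sum(tt * (.data$value - mean(.data$value))) / sum(tt^2)
    }, .groups = "drop")
  scenario |>
    inner_join(slopes, by = "cell") |>
    mutate(value = .data$value - .data$slope * (.data$time - min(times))) |>
    select(-"slope")
}

#' Relative climatic anomaly between two simulation periods
#'
#' The climatic anomaly of a predictor statistic is its relative change in
#' the simulation: future value divided by present value, per cell. Cells
#' where the present value is (numerically) zero get a missing anomaly
#' rather than an unbounded ratio; their count is reported.
#'
#' @param future,present tibbles with columns `cell`, `value`, both carrying
#'   a `predictor` attribute naming the statistic.
#' @param eps absolute present-value threshold below which the ratio is
#'   undefined.
#' @return tibble `cell`, `value` (= future/present) with attributes
#'   `predictor` and `n_undefined`.
#' @export
anomaly_ratio <- function(future, present, eps = 1e-6) {
  pf <- attr(future, "predictor"); pp <- attr(present, "predictor")
  if (!is.null(pf) && !is.null(pp) && !identical(pf, pp))
    abort(sprintf("anomaly_ratio: predictor mismatch (%s vs %s)", pf, pp))
  out <- inner_join(rename(future, f = "value"), rename(present, p = "value"),
                    by = "cell")
  undef <- abs(out$p) < eps
  out$value <- ifelse(undef, NA_real_, out$f / out$p)
  if (any(undef))
    warn(sprintf("anomaly_ratio: %d cell(s) with |present| < %g set to missing",
                 sum(undef), eps))
  out <- select(out, "cell", "value")
  attr(out, "predictor") <- pf %||% pp
  attr(out, "n_undefined") <- sum(undef)
  out
}

#' Regrid a stack to a coarser or finer nested geometry
#'
#' Coarsening by an integer factor aggregates each block of source cells by
#' its area-weighted mean over sea cells (all cells have equal area on the
#' planar grid); a target cell is sea when at least half of its source
#' block is sea. Refinement splits each source cell; continuous layers are
#' bilinearly interpolated between source cell centres, fraction layers
#' (e.g. `SAND`) inherit the containing source cell so block means are
#' preserved exactly.
#'
#' @param stack an [env_stack()].
#' @param factor integer aggregation factor (`2` halves both dimensions) or
#'   `1/k` notation via `refine` for splitting.
#' @param refine integer refinement factor; exactly one of `factor`/`refine`
#'   may exceed 1.
#' @param fraction_layers predictor names treated as area fractions.
#' @return an [env_stack()] on the new geometry.
#' @export
regrid_stack <- function(stack, factor = 1, refine = 1,
                         fraction_layers = intersect("SAND", stack_predictors(stack))) {
  stopifnot(factor >= 1, refine >= 1)
  if (factor > 1 && refine > 1) abort("regrid_stack: choose coarsening or refinement, not both")
  d <- stack_dims(stack)
  vars <- c("depth", stack_predictors(stack))
  if (factor == 1 && refine == 1) return(stack)
  if (factor > 1) {
    factor <- as.integer(factor)
    if (d[1] %% factor || d[2] %% factor)
      abort("regrid_stack: dimensions not divisible by factor")
    nd <- d %/% factor
    tab <- stack |>
      mutate(trow = (.data$row - 1L) %/% factor + 1L,
             tcol = (.data$col - 1L) %/% factor + 1L) |>
      group_by(.data$trow, .data$tcol) |>
      summarise(n_sea = n(), across(dplyr::all_of(vars), mean), .groups = "drop") |>
      filter(.data$n_sea >= factor^2 / 2) |>
      rename(row = "trow", col = "tcol") |>
      select(-"n_sea")
    return(env_stack(tab, dims = nd, predictors = stack_predictors(stack),
                     cell_km = attr(stack, "cell_km") * factor,
                     provenance = attr(stack, "provenance")))
  }
  refine <- as.integer(refine)
  nd <- d * refine
  sub <- expand.grid(dr = seq_len(refine), dc = seq_len(refine))
  tab <- purrr::pmap(sub, function(dr, dc) {
    mutate(as_tibble(stack),
           trow = (.data$row - 1L) * refine + dr,
           tcol = (.data$col - 1L) * refine + dc)
  }) |> bind_rows()
  # bilinear interpolation of continuous layers at new cell centres
  cont <- setdiff(vars, fraction_layers)
  src_rc <- seq_len(d[1]); src_cc <- seq_len(d[2])  # centre coords in source cell units
  t_r <- (tab$trow - 0.5) / refine + 0.5            # target centre in source-centre units
  t_c <- (tab$tcol - 0.5) / refine + 0.5
  for (v in cont) {
    m <- layer_matrix(stack, v)
    # fill NA (land) with nearest sea value per column mean so interpolation
    # near coasts stays finite; masked cells are dropped below anyway
    mfill <- m
    mfill[is.na(mfill)] <- mean(m, na.rm = TRUE)
    tab[[v]] <- pracma::interp2(src_cc, src_rc, mfill,
                                clamp(t_c, 1, d[2]), clamp(t_r, 1, d[1]))
  }
  tab <- tab |>
    select(-"row", -"col", -"cell", -"lat") |>   # lat is recomputed on the new grid
    rename(row = "trow", col = "tcol")
  env_stack(tab, dims = nd, predictors = stack_predictors(stack),
            cell_km = attr(stack, "cell_km") / refine,
            provenance = attr(stack, "provenance"))
}

#' Write / read a stack as plain-text tables
#'
#' Serialises the per-cell table as CSV alongside a YAML manifest holding
#' grid geometry, predictor names and provenance.
#'
#' @param stack an [env_stack()].
#' @param path directory to write into (created if needed).
#' @return `write_stack()` the path, invisibly; `read_stack()` an
#'   [env_stack()].
#' @export
write_stack <- function(stack, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as_tibble(stack), file.path(path, "cells.csv"), row.names = FALSE)
  yaml::write_yaml(list(dims = as.integer(stack_dims(stack)),
                        cell_km = attr(stack, "cell_km"),
                        predictors = stack_predictors(stack),
                        provenance = attr(stack, "provenance")),
                   file.path(path, "manifest.yml"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  man <- yaml::read_yaml(file.path(path, "manifest.yml"))
  cells <- as_tibble(utils::read.csv(file.path(path, "cells.csv")))
  env_stack(cells, dims = man$dims, predictors = man$predictors,
            cell_km = man$cell_km, provenance = man$provenance)
}
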