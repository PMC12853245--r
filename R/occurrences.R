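#' Thin occurrence records to one per grid cell
#'
#' Maps point records to grid cells and collapses duplicates, keeping one
#' record per species per cell. The coordinate convention is planar with
#' the origin at the grid's upper-left corner: `x` grows eastward along
#' columns, `y` grows southward along rows, cells are half-open intervals
#' `[x0, x0 + cell)` so a point on a shared edge belongs to the cell on its
#' right/below. Records with non-finite coordinates, outside the grid
#' extent, or on land/masked cells are dropped and counted.
#'
#' @param records tibble with columns `species_id`, `x`, `y` (km from the
#'   upper-left grid corner).
#' @param stack [env_stack()] defining geometry and the land/sea mask.
#' @return tibble `species_id`, `cell`, `row`, `col` (unique per species),
#'   with a `drop_counts` attribute
#'   (`source`, `invalid`, `off_grid`, `masked`, `duplicate`).
#' @export
thin_to_grid <- function(records, stack) {
  stopifnot(all(c("species_id", "x", "y") %in% names(records)))
  d <- stack_dims(stack); ck <- attr(stack, "cell_km")
  n0 <- nrow(records)
  fin <- is.finite(records$x) & is.finite(records$y)
  rec <- records[fin, , drop = FALSE]
  col <- floor(rec$x / ck) + 1L
  row <- floor(rec$y / ck) + 1L
  on_grid <- row >= 1L & row <= d[1] & col >= 1L & col <= d[2]
  rec <- rec[on_grid, ]; row <- row[on_grid]; col <- col[on_grid]
  cell <- cell_id(row, col, d)
  at_sea <- cell %in% stack$cell
  tab <- tibble(species_id = rec$species_id[at_sea],
                cell = cell[at_sea], row = as.integer(row[at_sea]),
                col = as.integer(col[at_sea]))
  out <- distinct(tab, .data$species_id, .data$cell, .keep_all = TRUE) |>
    arrange(.data$species_id, .data$cell)
  if (nrow(out) == 0) warn("thin_to_grid: no record fell on a valid sea cell")
  attr(out, "drop_counts") <- c(
    source = n0, invalid = n0 - sum(fin), off_grid = sum(fin) - sum(on_grid),
    masked = sum(on_grid) - sum(at_sea), duplicate = nrow(tab) - nrow(out))
  out
}

#' Minimum-prevalence species filter
#'
#' Retains species occupying at least `n_min` grid cells ("at least" —
#' the boundary is inclusive); sample sizes below that make distribution
#' models too fragile to project. Excluded species are reported.
#'
#' @param occurrences thinned occurrence tibble
#'   (`species_id`, `cell`, ...), e.g. from [thin_to_grid()].
#' @param n_min minimum number of occupied cells (default 120).
#' @return the retained rows, with an `excluded` attribute: tibble
#'   `species_id`, `n_cells` of the species that failed the filter.
#' @export
filter_min_cells <- function(occurrences, n_min = 120) {
  if (n_min < 1) abort("filter_min_cells: n_min must be >= 1")
  if (nrow(occurrences) == 0) {
    attr(occurrences, "excluded") <- tibble(species_id = character(), n_cells = integer())
    return(occurrences)
  }
  counts <- count(occurrences, .data$species_id, name = "n_cells")
  keep <- counts$species_id[counts$n_cells >= n_min]
  out <- filter(occurrences, .data$species_id %in% keep)
  attr(out, "excluded") <- filter(counts, !.data$species_id %in% keep)
  attr(out, "drop_counts") <- attr(occurrences, "drop_counts")
  out
}
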