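# Small worlds and hand-built stacks shared across tests.

# all-sea rectangular stack with hand-set layers; depth defaults shallow
toy_stack <- function(nr = 10, nc = 10, layers = list(), depth = NULL,
                      cell_km = 1, drop_cells = integer()) {
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  cells <- tibble::tibble(row = as.integer(grid$row), col = as.integer(grid$col))
  cells$depth <- if (is.null(depth)) rep(50, nrow(cells)) else depth
  if (!length(layers)) layers <- list(T_median = 20 - cells$row * 0.1)
  for (nm in names(layers)) cells[[nm]] <- layers[[nm]]
  if (length(drop_cells)) {
    id <- (cells$row - 1L) * nc + cells$col
    cells <- cells[!id %in% drop_cells, ]
  }
  env_stack(cells, dims = c(nr, nc), predictors = names(layers),
            cell_km = cell_km)
}

# binary_range from explicit (row, col) presences on a stack
toy_range <- function(stack, rows, cols, species_id = "sp", scenario = "base") {
  d <- stack_dims(stack)
  out <- tibble::tibble(cell = (rows - 1L) * d[2] + cols,
                        row = as.integer(rows), col = as.integer(cols))
  structure(out, species_id = species_id, scenario = scenario,
            threshold = 0.5, dims = d,
            class = c("binary_range", class(tibble::tibble())))
}

# cheap fitted ensemble on a small world: used by projection / importance /
# degenerate-input tests; cached per session
small_fitted <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    w <- generate_world(25, 30, seed = 11)
    sp <- make_virtual_species(w, "toy", thermal_optimum = 18, breadth = 1.5)
    occ <- sample_occurrences(sp, w, 80, seed = 3)
    pa <- build_pa_replicates(w, occ, n_total = 200, reps = 2, seed = 7)
    ens <- suppressWarnings(fit_sdm_ensemble(
      w, occ, pa, c("T_median", "SAL_median"), n_repeats = 1,
      k_blocks = 6, seed = 5, learners = c("glm", "rf")))
    cache <<- list(world = w, species = sp, occ = occ, pa = pa, ensemble = ens)
    cache
  }
})
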