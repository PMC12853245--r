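#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end run with the
#' pipeline defaults; unknown parameter names are rejected so typos fail
#' loudly. All values are echoed into the run manifest.
#'
#' @param ... overrides of the defaults listed below.
#' @return a `shift_config` list.
#' @export
shift_config <- function(...) {
  defaults <- list(
    # synthetic world / study design
    rows = 60, cols = 100, cell_km = 1,
    n_species = 6,
    cold_optima = c(14.9, 16.1, 17.3), warm_optima = c(20.3, 21.3, 22.3),
    breadth = 0.5,
    n_occurrences = 220, bias_decay_km = 5,
    scenarios = list(list(scenario = "rcp85", window = "far")),
    # predictor selection
    r_threshold = 0.7, vif_threshold = 10,
    priority = c("T_median", "O2_median", "CHL_median", "SAL_median",
                 "Vm_median", "SAND"),
    # occurrences / pseudo-absences
    n_min_cells = 120,
    pa_total = 1000, pa_split = 0.5, pa_reps = 3,
    # ensemble design
    n_folds = 5, n_repeats = 3, k_blocks = 10, eval_prop = 0.2,
    auc_min = 0.7, auc_ensemble_min = 0.75,
    importance_reps = 3, importance_rows = 250,
    # hotspots
    k_neighbors = 24, alpha_level = 0.001,
    master_seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    abort(paste0("shift_config: unknown parameter(s): ", paste(bad, collapse = ", ")))
  defaults[names(over)] <- over
  structure(defaults, class = "shift_config")
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage end to end on a simulated world: world generation,
#' virtual species and biased occurrence sampling, predictor selection,
#' pseudo-absence replicates, the spatially blocked four-learner ensemble,
#' projection onto baseline and scenario stacks (with max-TSS
#' binarization and the depth-window crop), per-species shift metrics and
#' EIVs, stacked alpha / temporal beta diversity, and Gi* hotspot
#' classification — alongside the analytic ground truth for every species.
#' Deterministic for a fixed `master_seed`.
#'
#' @param config a [shift_config()].
#' @param outdir optional directory; when given, metric tables are written
#'   as CSV together with a YAML run manifest echoing the full
#'   configuration.
#' @param quiet suppress progress messages.
#' @return a list with elements `world`, `species`, `occurrences`,
#'   `selection`, `ensembles`, `projections`, `shift_table`, `truth_table`,
#'   `eiv_table`, `importance_table`, `mess_table` (extrapolated cells per
#'   species and scenario), `eiv_screen`, `driver_bins`, `community`,
#'   `hotspots`, `config`.
#' @export
run_pipeline <- function(config = shift_config(), outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  seed <- config$master_seed
  say("stage simulate: %dx%d world, %d species", config$rows, config$cols,
      config$n_species)
  world <- generate_world(config$rows, config$cols, seed = seed,
                          cell_km = config$cell_km)
  optima <- c(config$cold_optima, config$warm_optima)[seq_len(config$n_species)]
  species <- purrr::imap(optima, function(opt, i)
    make_virtual_species(world, id = sprintf("sp%02d", i), thermal_optimum = opt,
                         breadth = config$breadth))
  names(species) <- purrr::map_chr(species, "id")
  bias <- coastal_bias(world, config$bias_decay_km)
  occ_all <- purrr::map(species, function(sp)
    sample_occurrences(sp, world, config$n_occurrences, bias = bias,
                       seed = derive_seed(seed, sp$id))) |> bind_rows()

  say("stage prep: thinning + %d-cell filter", config$n_min_cells)
  occ_all <- filter_min_cells(occ_all, config$n_min_cells)
  kept <- unique(occ_all$species_id)
  species <- species[kept]

  say("stage select: correlation clusters + VIF")
  selection <- select_predictors(world, r_threshold = config$r_threshold,
                                 priority = config$priority,
                                 vif_threshold = config$vif_threshold)
  predictors <- selection$retained

  scen_stacks <- purrr::map(config$scenarios, function(s) {
    apply_anomaly(world, make_anomaly(world, s$scenario, s$window))
  })
  names(scen_stacks) <- purrr::map_chr(scen_stacks, attr, "provenance")

  ensembles <- list(); projections <- list()
  shift_rows <- list(); truth_rows <- list(); eiv_rows <- list(); imp_rows <- list()
  mess_rows <- list()
  ranges_base <- list(); ranges_fut <- purrr::map(scen_stacks, function(x) list())
  maps_base <- list(); maps_fut <- purrr::map(scen_stacks, function(x) list())

  for (sid in names(species)) {
    sp <- species[[sid]]
    occ <- filter(occ_all, .data$species_id == sid)
    say("stage pa+fit: %s (%d occurrence cells)", sid, nrow(occ))
    pa <- build_pa_replicates(world, occ, target_group = occ_all,
                              n_total = config$pa_total, split = config$pa_split,
                              reps = config$pa_reps,
                              seed = derive_seed(seed, paste0("pa_", sid)))
    ens <- fit_sdm_ensemble(world, occ, pa, predictors,
                            n_folds = config$n_folds, n_repeats = config$n_repeats,
                            k_blocks = config$k_blocks, eval_prop = config$eval_prop,
                            auc_min = config$auc_min,
                            auc_ensemble_min = config$auc_ensemble_min,
                            seed = derive_seed(seed, paste0("fit_", sid)),
                            species_id = sid)
    ensembles[[sid]] <- ens
    if (!ens$usable) next
    imp <- permutation_importance(ens, reps = config$importance_reps,
                                  seed = derive_seed(seed, paste0("imp_", sid)),
                                  n_rows = config$importance_rows)
    imp_rows[[sid]] <- mutate(imp, species_id = sid)

    say("stage project: %s", sid)
    map_b <- project_ensemble(ens, world)
    rng_b <- binarize_map(map_b)
    maps_base[[sid]] <- map_b
    ranges_base[[sid]] <- rng_b
    met_b <- range_metrics(rng_b, world)
    frg_b <- fragmentation(rng_b, world)
    met_b$FRAG <- frg_b$FRAG
    eiv_rows[[sid]] <- eiv_profile(occ, world, predictors, frag = frg_b$FRAG)
    truth_b <- true_range_metrics(sp, world)

    for (sc in names(scen_stacks)) {
      stk <- scen_stacks[[sc]]
      map_f <- project_ensemble(ens, stk)
      rng_f <- depth_crop(binarize_map(map_f), stk, baseline_occurrences = occ)
      maps_fut[[sc]][[sid]] <- map_f
      ranges_fut[[sc]][[sid]] <- rng_f
      mess_rows[[paste(sid, sc)]] <- mess_grid(stk, bind_rows(ens$tables),
                                               predictors) |>
        mutate(species_id = sid, scenario = sc) |>
        filter(.data$mess < 0)   # store only extrapolated (novel) cells
      met_f <- range_metrics(rng_f, stk)
      met_f$FRAG <- fragmentation(rng_f, stk)$FRAG
      shift_rows[[paste(sid, sc)]] <- shift_metrics(met_b, met_f) |>
        mutate(scenario = sc,
               RANGE_base = met_b$RANGE, LAT_base = met_b$LAT,
               DEPTH_base = met_b$DEPTH, FRAG_base = met_b$FRAG)
      # analytic truth under the same scenario
      truth_f <- true_range_metrics(sp, stk)
      truth_rows[[paste(sid, sc)]] <- tibble(
        species_id = sid, scenario = sc,
        cold_adapted = sp$thermal_optimum < median(world$T_median),
        RANGE_true_base = truth_b$RANGE, RANGE_true_fut = truth_f$RANGE,
        dRANGE_true = 100 * (truth_f$RANGE - truth_b$RANGE) / truth_b$RANGE,
        dLAT_true = truth_f$LAT - truth_b$LAT,
        dDEPTH_true = truth_f$DEPTH - truth_b$DEPTH)
    }
    projections[[sid]] <- list(baseline = map_b)
    # projections and importance are done: drop the fitted member models,
    # which dominate memory (the scores and metric tables remain)
    ens$members <- NULL
    ensembles[[sid]] <- ens
  }

  shift_table <- bind_rows(shift_rows)
  truth_table <- bind_rows(truth_rows)
  eiv_table <- bind_rows(eiv_rows)
  importance_table <- bind_rows(imp_rows)
  mess_table <- bind_rows(mess_rows)

  # species-level syntheses: EIV correlation screen and driver binning
  eiv_screen <- if (nrow(shift_table) >= 5 && nrow(eiv_table) >= 5)
    eiv_correlation_screen(shift_table, eiv_table) else NULL
  driver_bins <- if (nrow(importance_table) && nrow(shift_table))
    driver_binning(importance_table, shift_table) else NULL

  say("stage diversity + hotspots")
  community <- list(); hotspot_list <- list()
  if (length(maps_base) >= 2) {
    alpha_b <- alpha_stack(maps_base)
    for (sc in names(scen_stacks)) {
      alpha_f <- alpha_stack(maps_fut[[sc]])
      da <- delta_alpha(alpha_f, alpha_b)
      beta <- temporal_beta(ranges_base, ranges_fut[[sc]], world)
      z_da <- getis_gstar(rename(da, value = "delta_alpha"), config$k_neighbors)
      z_abs <- getis_gstar(mutate(rename(da, value = "delta_alpha"),
                                  value = abs(.data$value)), config$k_neighbors)
      z_tu <- getis_gstar(select(mutate(beta, value = .data$beta_tu),
                                 "cell", "row", "col", "value"),
                          config$k_neighbors)
      community[[sc]] <- list(alpha_baseline = alpha_b, alpha_future = alpha_f,
                              delta_alpha = da, beta = beta)
      hotspot_list[[sc]] <- classify_hotspots(z_da, z_abs, z_tu,
                                              config$alpha_level)
    }
  }

  result <- list(world = world, species = species, occurrences = occ_all,
                 selection = selection, ensembles = ensembles,
                 projections = projections,
                 ranges_base = ranges_base, ranges_future = ranges_fut,
                 maps_base = maps_base, maps_future = maps_fut,
                 shift_table = shift_table, truth_table = truth_table,
                 eiv_table = eiv_table, importance_table = importance_table,
                 mess_table = mess_table, eiv_screen = eiv_screen,
                 driver_bins = driver_bins,
                 community = community, hotspots = hotspot_list,
                 config = config)
  if (!is.null(outdir)) write_run(result, outdir)
  result
}

# Persist metric tables + manifest as plain text.
write_run <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, nm) if (!is.null(x) && nrow(x))
    utils::write.csv(x, file.path(outdir, nm), row.names = FALSE)
  wr(result$shift_table, "shift_metrics.csv")
  wr(result$truth_table, "truth_metrics.csv")
  wr(result$eiv_table, "eiv_profiles.csv")
  wr(result$importance_table, "importance.csv")
  wr(result$mess_table, "mess_novel_cells.csv")
  wr(result$eiv_screen, "eiv_screen.csv")
  wr(result$driver_bins, "driver_bins.csv")
  wr(as_tibble(result$occurrences), "occurrences.csv")
  for (sc in names(result$community)) {
    wr(result$community[[sc]]$delta_alpha, paste0("delta_alpha_", sc, ".csv"))
    wr(result$community[[sc]]$beta, paste0("beta_", sc, ".csv"))
    wr(as_tibble(result$hotspots[[sc]]), paste0("hotspots_", sc, ".csv"))
  }
  yaml::write_yaml(list(config = unclass(result$config),
                        predictors = result$selection$retained,
                        species = names(result$species)),
                   file.path(outdir, "run_manifest.yml"))
  invisible(outdir)
}
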