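#' k-medoid spatial blocks
#'
#' Partitions cell coordinates into `k` spatially contiguous blocks by
#' k-medoids (PAM) on Euclidean grid coordinates, the splitting unit for
#' spatially independent train/evaluation and cross-validation folds.
#' PAM's build+swap algorithm is deterministic for a given input.
#'
#' @param cells tibble with `row`, `col` (one row per data point).
#' @param k number of blocks (>= 2).
#' @return integer block labels, one per row of `cells`.
#' @export
spatial_blocks <- function(cells, k = 10) {
  if (k < 2) abort("spatial_blocks: k must be >= 2")
  xy <- cbind(cells$row, cells$col)
  if (nrow(unique(xy)) < k)
    abort("spatial_blocks: fewer distinct locations than blocks")
  cluster::pam(xy, k = k, metric = "euclidean", cluster.only = TRUE,
               pamonce = 5)
}

# Allocate whole blocks to the evaluation hold-out until it reaches ~prop
# of the data; seeded shuffle makes the allocation reproducible.
allocate_eval_blocks <- function(blocks, prop = 0.2, seed = 1) {
  tab <- table(blocks)
  ids <- with_seed(seed, sample(names(tab)))
  csum <- cumsum(as.numeric(tab[ids])) / length(blocks)
  take <- ids[seq_len(max(1, which.min(abs(csum - prop))))]
  blocks %in% as.integer(take)
}

# Assign training blocks to `nfolds` CV folds, shuffled by seed, greedily
# balancing fold sizes.
assign_folds <- function(blocks, nfolds = 5, seed = 1) {
  tab <- sort(table(blocks), decreasing = TRUE)
  ids <- with_seed(seed, sample(names(tab), length(tab), prob = rep(1, length(tab))))
  tab <- tab[ids]
  fold_of <- integer(0)
  sizes <- numeric(nfolds)
  for (b in names(tab)) {
    f <- which.min(sizes)
    fold_of[b] <- f
    sizes[f] <- sizes[f] + tab[[b]]
  }
  unname(fold_of[as.character(blocks)])
}

#' Assemble a presence / pseudo-absence training table
#'
#' Joins presences (label 1) and one pseudo-absence replicate (label 0)
#' with predictor values at their cells, weighting pseudo-absences so the
#' weighted prevalence is equal (sum of presence weights equals sum of
#' pseudo-absence weights).
#'
#' @param stack baseline [env_stack()].
#' @param occurrences focal presences (`cell`).
#' @param pa pseudo-absence cells for one replicate (`cell`).
#' @param predictors predictor columns to carry.
#' @return tibble `cell`, `row`, `col`, `label`, `weight`, predictors.
#' @export
build_training_table <- function(stack, occurrences, pa, predictors) {
  pres <- tibble(cell = unique(occurrences$cell), label = 1L)
  abs_ <- tibble(cell = pa$cell, label = 0L)
  tab <- bind_rows(pres, abs_) |>
    inner_join(select(as_tibble(stack), "cell", "row", "col", "lat", "depth",
                      dplyr::all_of(predictors)), by = "cell")
  if (nrow(tab) < nrow(pres) + nrow(abs_))
    abort("build_training_table: some cells missing from the stack")
  n1 <- sum(tab$label == 1); n0 <- sum(tab$label == 0)
  tab$weight <- ifelse(tab$label == 1, 1, n1 / n0)
  tab
}

learner_types <- c("glm", "gam", "rf", "ann")

#' Fit one ensemble member
#'
#' Fits one of the four learners on a calibration table, at the
#' intermediate complexity the pipeline prescribes:
#' * `glm` — binomial GLM with linear and quadratic terms;
#' * `gam` — binomial GAM, smooth basis complexity 3 per predictor;
#' * `rf` — random forest (1000 trees, terminal nodes >= 40, 2 candidate
#'   predictors per split) grown on the 0/1 response;
#' * `ann` — feed-forward neural network (8 hidden units, weight decay 0.1).
#'
#' Predictors are standardised on the calibration data (stored with the
#' member); case weights keep the weighted prevalence equal.
#'
#' @param learner one of `"glm"`, `"gam"`, `"rf"`, `"ann"`.
#' @param data calibration rows of a [build_training_table()].
#' @param predictors predictor names.
#' @param seed integer seed (RF bootstrap, ANN initialisation).
#' @return an `sdm_member` (list: `learner`, `fit`, `center`, `scale`,
#'   `predictors`), or `NULL` with a warning if only one class is present.
#' @export
fit_member <- function(learner, data, predictors, seed = 1) {
  learner <- match.arg(learner, learner_types)
  if (length(unique(data$label)) < 2) {
    warn(sprintf("fit_member(%s): single-class calibration data; member skipped", learner))
    return(NULL)
  }
  x <- as.data.frame(data[predictors])
  ctr <- vapply(x, mean, numeric(1))
  scl <- vapply(x, sd, numeric(1)); scl[scl == 0] <- 1
  xs <- as.data.frame(scale(x, ctr, scl))
  df <- cbind(label = data$label, xs)
  w <- data$weight
  fit <- with_seed(seed, switch(
    learner,
    glm = {
      rhs <- paste(c(predictors, paste0("I(", predictors, "^2)")), collapse = " + ")
      suppressWarnings(stats::glm(stats::as.formula(paste("label ~", rhs)),
                                  data = df, family = stats::binomial(),
                                  weights = w))
    },
    gam = {
      rhs <- paste(sprintf("s(%s, k = 3)", predictors), collapse = " + ")
      suppressWarnings(mgcv::gam(stats::as.formula(paste("label ~", rhs)),
                                 data = df, family = stats::binomial(),
                                 weights = w))
    },
    rf = ranger::ranger(
      y = data$label, x = xs, num.trees = 1000, min.node.size = 40,
      mtry = min(2, length(predictors)), case.weights = w,
      num.threads = 1, seed = seed),
    ann = nnet::nnet(xs, data$label, weights = w, size = 8, decay = 0.1,
                     maxit = 200, entropy = TRUE, trace = FALSE)))
  structure(list(learner = learner, fit = fit, center = ctr, scale = scl,
                 predictors = predictors),
            class = "sdm_member")
}

#' @rdname fit_member
#' @param member an `sdm_member`.
#' @param newdata data frame with the member's predictor columns.
#' @return numeric suitability in \[0, 1\].
#' @export
predict_member <- function(member, newdata) {
  xs <- as.data.frame(scale(as.data.frame(newdata[member$predictors]),
                            member$center, member$scale))
  p <- switch(member$learner,
              glm = predict(member$fit, xs, type = "response"),
              gam = as.numeric(predict(member$fit, xs, type = "response")),
              rf = predict(member$fit, xs, num.threads = 1)$predictions,
              ann = as.numeric(predict(member$fit, xs)))
  clamp(as.numeric(p), 0, 1)
}

#' Fit the full spatially blocked ensemble for one species
#'
#' Runs the complete design: for each pseudo-absence replicate, cells are
#' split into k-medoid spatial blocks, ~20% of blocks (by cell count) are
#' held out for evaluation, and the remaining blocks are folded into a
#' 5-fold block-wise cross-validation repeated `n_repeats` times; each
#' calibration set is fitted with all four learners
#' (5 folds x 3 repetitions x 3 replicates x 4 learners = 180 attempted
#' members by default). Every member is scored (AUC, TSS) on calibration,
#' validation and evaluation data; members with evaluation AUC strictly
#' above `auc_min` are retained and averaged (unweighted) into the
#' ensemble. The ensemble is scored on training and pooled evaluation data,
#' the continuous Boyce index is computed against the full background, and
#' the species is flagged unusable when ensemble evaluation AUC does not
#' exceed `auc_ensemble_min`. A max-TSS binarization threshold is fixed on
#' the baseline evaluation predictions for reuse across scenarios.
#'
#' @param stack baseline [env_stack()].
#' @param occurrences focal presences (`cell`, `row`, `col`).
#' @param pa_replicates pseudo-absence tibble from [build_pa_replicates()].
#' @param predictors retained predictor names.
#' @param n_folds,n_repeats cross-validation design (5 x 3).
#' @param k_blocks number of k-medoid spatial blocks per replicate.
#' @param eval_prop target evaluation share (0.2).
#' @param learners learner subset (default all four).
#' @param auc_min member retention threshold (evaluation AUC > 0.7).
#' @param auc_ensemble_min ensemble usability threshold (> 0.75).
#' @param seed master seed; all fold/member seeds derive from it.
#' @param species_id identifier carried through outputs.
#' @return an `sdm_ensemble` (see [build_ensemble()]).
#' @export
fit_sdm_ensemble <- function(stack, occurrences, pa_replicates, predictors,
                             n_folds = 5, n_repeats = 3, k_blocks = 10,
                             eval_prop = 0.2, learners = learner_types,
                             auc_min = 0.7, auc_ensemble_min = 0.75,
                             seed = 1,
                             species_id = occurrences$species_id[1] %||% "species") {
  members <- list(); scores <- list(); mi <- 0L
  eval_pool <- list()
  tables <- list()
  reps <- sort(unique(pa_replicates$replicate))
  for (r in reps) {
    pa <- filter(pa_replicates, .data$replicate == r)
    tab <- build_training_table(stack, occurrences, pa, predictors)
    blocks <- spatial_blocks(tab, k = k_blocks)
    in_eval <- allocate_eval_blocks(blocks, eval_prop,
                                    seed = derive_seed(seed, paste0("eval_", r)))
    tab$block <- blocks
    tab$in_eval <- in_eval
    tables[[as.character(r)]] <- tab
    eval_tab <- tab[tab$in_eval, ]
    train_tab <- tab[!tab$in_eval, ]
    for (rep_i in seq_len(n_repeats)) {
      folds <- assign_folds(train_tab$block, nfolds = n_folds,
                            seed = derive_seed(seed, paste0("fold_", r, "_", rep_i)))
      for (f in seq_len(n_folds)) {
        calib <- train_tab[folds != f, ]
        valid <- train_tab[folds == f, ]
        for (lr in learners) {
          mi <- mi + 1L
          mseed <- derive_seed(seed, paste0("member_", r, "_", rep_i, "_", f, "_", lr))
          mem <- fit_member(lr, calib, predictors, seed = mseed)
          meta <- tibble(member = mi, learner = lr, replicate = r,
                         repetition = rep_i, fold = f)
          if (is.null(mem)) {
            scores[[mi]] <- mutate(meta, auc_calibration = NA_real_,
                                   auc_validation = NA_real_, auc_evaluation = NA_real_,
                                   tss_evaluation = NA_real_, skipped = TRUE)
            members[[mi]] <- list(NULL)
            next
          }
          p_cal <- predict_member(mem, calib)
          p_val <- if (nrow(valid)) predict_member(mem, valid) else numeric()
          p_ev <- predict_member(mem, eval_tab)
          ts <- tss_max(p_ev, eval_tab$label)
          scores[[mi]] <- mutate(
            meta,
            auc_calibration = auc_score(p_cal, calib$label),
            auc_validation = if (nrow(valid)) auc_score(p_val, valid$label) else NA_real_,
            auc_evaluation = auc_score(p_ev, eval_tab$label),
            tss_evaluation = ts$tss, skipped = FALSE)
          members[[mi]] <- mem
        }
      }
    }
  }
  score_tab <- bind_rows(scores)
  build_ensemble(members, score_tab, tables,
                 stack = stack, predictors = predictors,
                 occurrences = occurrences, auc_min = auc_min,
                 auc_ensemble_min = auc_ensemble_min, species_id = species_id,
                 design = list(n_folds = n_folds, n_repeats = n_repeats,
                               n_replicates = length(reps),
                               n_learners = length(learners),
                               attempted = mi, seed = seed))
}

#' Assemble the retained-member ensemble
#'
#' Applies the retention rule (evaluation AUC strictly greater than
#' `auc_min`), averages retained members into the committee, scores the
#' ensemble on training and pooled evaluation data, computes the Boyce
#' index against the full-background suitability, fixes the max-TSS
#' binarization threshold on evaluation data, and flags the species
#' unusable when ensemble evaluation AUC is not above `auc_ensemble_min`.
#' Normally called via [fit_sdm_ensemble()].
#'
#' @param members list of `sdm_member` objects (skipped ones as `NULL`).
#' @param scores per-member score tibble.
#' @param tables named list of per-replicate training tables.
#' @param stack,predictors,occurrences,species_id as in [fit_sdm_ensemble()].
#' @param auc_min,auc_ensemble_min retention / usability thresholds.
#' @param design design metadata list.
#' @return an `sdm_ensemble` list: `species_id`, `members`, `scores`
#'   (with `retained` flags), `retained` indices, `usable`, `ensemble_scores`,
#'   `boyce`, `threshold`, `tables`, `predictors`, `design`.
#' @export
build_ensemble <- function(members, scores, tables, stack, predictors,
                           occurrences, auc_min = 0.7, auc_ensemble_min = 0.75,
                           species_id = "species", design = list()) {
  scores$retained <- !is.na(scores$auc_evaluation) & scores$auc_evaluation > auc_min
  retained <- scores$member[scores$retained]
  ens <- structure(
    list(species_id = species_id, members = members, scores = scores,
         retained = retained, predictors = predictors, tables = tables,
         design = design, auc_min = auc_min,
         auc_ensemble_min = auc_ensemble_min, usable = FALSE,
         ensemble_scores = NULL, boyce = NA_real_, threshold = NA_real_),
    class = "sdm_ensemble")
  if (!length(retained)) {
    warn(sprintf("species %s: no member retained (evaluation AUC <= %.2f); unmodelled",
                 species_id, auc_min))
    return(ens)
  }
  # pooled evaluation rows across replicates
  eval_rows <- bind_rows(lapply(tables, function(t) t[t$in_eval, ]))
  train_rows <- bind_rows(lapply(tables, function(t) t[!t$in_eval, ]))
  # training-stage score on a capped, seeded row subsample; the score is a
  # summary, not part of the fit
  if (nrow(train_rows) > 1500)
    train_rows <- with_seed(derive_seed(design$seed %||% 1, "train_score"),
                            train_rows[sample(nrow(train_rows), 1500), ])
  p_eval <- ensemble_predict(ens, eval_rows)
  p_train <- ensemble_predict(ens, train_rows)
  ts <- tss_max(p_eval, eval_rows$label)
  ens$ensemble_scores <- bind_rows(
    score_predictions(p_train, train_rows$label, "training"),
    score_predictions(p_eval, eval_rows$label, "evaluation"))
  ens$threshold <- ts$threshold
  bg <- ensemble_predict(ens, stack)
  # cache the baseline full-stack committee prediction; project_ensemble()
  # reuses it so the training stack is never predicted twice
  ens$baseline_prediction <- tibble(cell = stack$cell, suitability = bg)
  ens$baseline_provenance <- attr(stack, "provenance")
  pres_suit <- bg[match(unique(occurrences$cell), stack$cell)]
  ens$boyce <- boyce_index(pres_suit[!is.na(pres_suit)], bg)
  auc_eval <- ens$ensemble_scores$auc[ens$ensemble_scores$stage == "evaluation"]
  ens$usable <- isTRUE(auc_eval > auc_ensemble_min)
  if (!ens$usable)
    warn(sprintf("species %s: ensemble evaluation AUC %.3f <= %.2f; flagged unusable",
                 species_id, auc_eval, auc_ensemble_min))
  ens
}

# mean suitability over retained members
ensemble_predict <- function(ensemble, newdata) {
  stopifnot(length(ensemble$retained) > 0)
  p <- numeric(nrow(newdata))
  for (m in ensemble$retained)
    p <- p + predict_member(ensemble$members[[m]], newdata)
  p / length(ensemble$retained)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %s: %d/%d members retained (AUC > %.2f); %s\n",
              x$species_id, length(x$retained), nrow(x$scores), x$auc_min,
              if (x$usable) "usable" else "unusable"))
  if (!is.null(x$ensemble_scores)) print(x$ensemble_scores)
  invisible(x)
}

#' Permutation importance of ensemble predictors
#'
#' For each predictor, its column is permuted, ensemble predictions are
#' recomputed, and importance is `1 - |Pearson rho|` between original and
#' permuted predictions, averaged over `reps` permutation rounds.
#' Predictors the ensemble ignores leave predictions unchanged
#' (rho = 1, importance 0). Computed on a seeded subsample of the species'
#' presence / pseudo-absence rows.
#'
#' @param ensemble a usable `sdm_ensemble`.
#' @param reps permutation rounds per predictor (3).
#' @param seed integer seed.
#' @param n_rows maximum number of training rows used.
#' @return tibble `predictor`, `importance`, `rank` (ties broken by
#'   predictor name).
#' @export
permutation_importance <- function(ensemble, reps = 3, seed = 1, n_rows = 500) {
  if (!length(ensemble$retained)) abort("permutation_importance: ensemble has no retained members")
  tab <- bind_rows(ensemble$tables)
  if (nrow(tab) > n_rows)
    tab <- with_seed(derive_seed(seed, "imp_rows"),
                     tab[sample(nrow(tab), n_rows), ])
  p0 <- ensemble_predict(ensemble, tab)
  imp <- vapply(ensemble$predictors, function(pr) {
    rhos <- vapply(seq_len(reps), function(k) {
      perm <- tab
      perm[[pr]] <- with_seed(derive_seed(seed, paste0("imp_", pr, "_", k)),
                              sample(perm[[pr]]))
      p1 <- ensemble_predict(ensemble, perm)
      if (sd(p1) == 0 || sd(p0) == 0) {
        warn("permutation_importance: zero-variance predictions; importance 0")
        return(1)
      }
      cor(p0, p1)
    }, numeric(1))
    mean(1 - abs(rhos))
  }, numeric(1))
  tibble(predictor = names(imp), importance = unname(imp)) |>
    arrange(dplyr::desc(.data$importance), .data$predictor) |>
    mutate(rank = row_number())
}
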