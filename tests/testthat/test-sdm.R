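# Spatial blocks, learners, ensemble assembly, permutation importance.

test_that("k-medoid blocks recover well-separated point clouds", {
  set.seed(31)
  centres <- cbind(c(10, 10, 60, 60, 35), c(10, 60, 10, 60, 35))
  pts <- do.call(rbind, lapply(1:5, function(i)
    cbind(centres[i, 1] + rnorm(40), centres[i, 2] + rnorm(40))))
  cells <- tibble::tibble(row = pts[, 1], col = pts[, 2],
                          truth = rep(1:5, each = 40))
  bl <- spatial_blocks(cells, k = 5)
  # every generated cloud maps to exactly one block
  tab <- table(cells$truth, bl)
  expect_true(all(apply(tab > 0, 1, sum) == 1))
  expect_error(spatial_blocks(cells, k = 1), "k must be")
  expect_identical(bl, spatial_blocks(cells, k = 5))
  dup <- tibble::tibble(row = rep(1, 5), col = rep(1, 5))
  expect_error(spatial_blocks(dup, k = 2), "distinct")
})

test_that("all four learners separate a separable 1-D toy", {
  set.seed(32)
  n <- 200
  x <- c(runif(n, 0.5, 3), runif(n, -3, -0.5))
  tab <- tibble::tibble(x = x, noise = rnorm(2 * n),
                        label = rep(c(1L, 0L), each = n), weight = 1)
  for (lr in c("glm", "gam", "rf", "ann")) {
    mem <- fit_member(lr, tab, c("x", "noise"), seed = 1)
    expect_s3_class(mem, "sdm_member")
    p <- predict_member(mem, tab)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auc_score(p, tab$label), 0.95)
  }
})

test_that("label-shuffled data scores near chance on held-out data", {
  set.seed(33)
  n <- 400
  tab <- tibble::tibble(x = rnorm(n), y = rnorm(n),
                        label = sample(rep(c(1L, 0L), n / 2)), weight = 1)
  train <- tab[1:300, ]; test <- tab[301:400, ]
  for (lr in c("glm", "rf")) {
    mem <- fit_member(lr, train, c("x", "y"), seed = 2)
    a <- auc_score(predict_member(mem, test), test$label)
    expect_gt(a, 0.35); expect_lt(a, 0.65)
  }
})

test_that("case weights equalise class totals however many absences", {
  w <- toy_stack(10, 10)
  occ <- tibble::tibble(cell = w$cell[1:20])
  pa1 <- tibble::tibble(cell = w$cell[21:60])
  pa2 <- tibble::tibble(cell = w$cell[21:100])  # doubled pseudo-absences
  t1 <- build_training_table(w, occ, pa1, "T_median")
  t2 <- build_training_table(w, occ, pa2, "T_median")
  expect_equal(sum(t1$weight[t1$label == 1]), sum(t1$weight[t1$label == 0]))
  expect_equal(sum(t2$weight[t2$label == 1]), sum(t2$weight[t2$label == 0]))
  # halved per-point weight when the absence count doubles
  expect_equal(t2$weight[t2$label == 0][1], t1$weight[t1$label == 0][1] / 2)
  mem <- fit_member("glm", t1, "T_median", seed = 1)
  expect_null(suppressWarnings(fit_member("glm", t1[t1$label == 1, ], "T_median")))
})

test_that("member retention and the usability flag follow the strict rules", {
  fx <- small_fitted()
  ens <- fx$ensemble
  sc <- ens$scores
  expect_equal(sc$retained,
               !is.na(sc$auc_evaluation) & sc$auc_evaluation > 0.7)
  ev <- ens$ensemble_scores$auc[ens$ensemble_scores$stage == "evaluation"]
  expect_equal(ens$usable, ev > 0.75)
  # ensemble prediction is the unweighted mean of retained members
  newdata <- as_tibble(fx$world)[1:50, ]
  per_member <- vapply(ens$retained, function(m)
    predict_member(ens$members[[m]], newdata), numeric(50))
  expect_equal(seashift:::ensemble_predict(ens, newdata), rowMeans(per_member))
  # glance reports the design bookkeeping
  g <- glance(ens)
  expect_equal(g$n_attempted, nrow(sc))
  expect_equal(g$n_retained, sum(sc$retained))
})

test_that("retention arithmetic: AUCs {0.65, 0.72, 0.80} keep two members", {
  aucs <- c(0.65, 0.72, 0.80)
  expect_equal(sum(aucs > 0.7), 2L)
  # and the boundary is strict
  expect_equal(sum(c(0.7, 0.700001) > 0.7), 1L)
})

test_that("permutation importance finds the niche predictor and ignores unused ones", {
  fx <- small_fitted()
  ens <- fx$ensemble
  imp <- permutation_importance(ens, seed = 3, n_rows = 300)
  expect_equal(imp$predictor[imp$rank == 1], "T_median")
  expect_gt(imp$importance[imp$predictor == "T_median"], 0.3)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  # a predictor no member uses leaves predictions unchanged: importance 0
  ens2 <- ens
  ens2$predictors <- c(ens$predictors, "depth")
  imp2 <- permutation_importance(ens2, seed = 3, n_rows = 300)
  expect_equal(imp2$importance[imp2$predictor == "depth"], 0)
  # stability across permutation seeds
  imps <- vapply(1:5, function(s)
    permutation_importance(ens, seed = s, n_rows = 300)$importance[1], numeric(1))
  expect_lt(max(imps) - min(imps), 0.1)
})

test_that("the blocked design attempts exactly folds x repeats x replicates x learners", {
  fx <- small_fitted()
  ens <- fx$ensemble
  # 5 folds x 1 repetition x 2 replicates x 2 learners
  expect_equal(nrow(ens$scores), 5L * 1L * 2L * 2L)
  expect_equal(ens$design$attempted, 20L)
  # evaluation cells never appear in any calibration fold
  for (r in names(ens$tables)) {
    t <- ens$tables[[r]]
    expect_gt(sum(t$in_eval), 0)
    whole <- tapply(t$in_eval, t$block, function(v) length(unique(v)))
    expect_true(all(whole == 1))  # blocks move to evaluation whole, or not at all
  }
})
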