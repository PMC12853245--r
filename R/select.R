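#' Cluster predictors by rank correlation
#'
#' Hierarchical clustering of candidate predictors on the dissimilarity
#' `1 - |Spearman r|`, with the tree cut at height `1 - r_threshold`
#' (default 0.3, i.e. predictors correlated above |r| = 0.7 fall in one
#' cluster). One representative is retained per cluster: the first match
#' in `priority` if given (the ecological-interpretability hook), otherwise
#' the member most correlated with its own cluster on average. Constant
#' layers have undefined correlations; they are isolated into singleton
#' clusters with a warning.
#'
#' @param stack an [env_stack()].
#' @param predictors candidate predictor names (default: all in the stack).
#' @param r_threshold correlation threshold defining the cut (0.7).
#' @param linkage agglomeration method for [stats::hclust()] ("average").
#' @param priority character vector; within each cluster the first present
#'   name is retained.
#' @return a `predictor_selection` list: `cor_matrix`, `tree` (hclust),
#'   `clusters` tibble (`predictor`, `cluster`, `representative`),
#'   `retained` character vector.
#' @export
correlation_clusters <- function(stack, predictors = stack_predictors(stack),
                                 r_threshold = 0.7, linkage = "average",
                                 priority = NULL) {
  if (length(predictors) < 2) abort("correlation_clusters: need >= 2 predictors")
  x <- as.data.frame(as_tibble(stack)[predictors])
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 10) abort("correlation_clusters: need >= 10 complete cells")
  const <- vapply(x, function(v) sd(v) == 0, logical(1))
  if (any(const))
    warn(paste0("constant layer(s) isolated into singleton clusters: ",
                paste(predictors[const], collapse = ", ")))
  r <- suppressWarnings(cor(x, method = "spearman"))
  r[is.na(r)] <- 0; diag(r) <- 1
  dmat <- 1 - abs(r)
  tree <- stats::hclust(stats::as.dist(dmat), method = linkage)
  grp <- stats::cutree(tree, h = 1 - r_threshold)
  reps <- vapply(split(names(grp), grp), function(members) {
    if (!is.null(priority)) {
      hit <- priority[priority %in% members]
      if (length(hit)) return(hit[1])
    }
    if (length(members) == 1) return(members)
    # highest mean |r| with the rest of its own cluster
    score <- vapply(members, function(m)
      mean(abs(r[m, setdiff(members, m)])), numeric(1))
    members[order(-score, members)][1]
  }, character(1))
  clusters <- tibble(predictor = names(grp), cluster = unname(grp),
                     representative = unname(reps[as.character(grp)]))
  structure(list(cor_matrix = r, tree = tree, clusters = clusters,
                 retained = unique(clusters$representative),
                 r_threshold = r_threshold),
            class = "predictor_selection")
}

#' Stepwise VIF pruning
#'
#' Iteratively removes the predictor with the largest variance inflation
#' factor (`VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on all
#' others over sea cells) until every remaining VIF is below `vif_threshold`.
#' Perfectly collinear predictors report `VIF = Inf` and are dropped first;
#' ties are broken by dropping the lexicographically last name.
#'
#' @param stack an [env_stack()].
#' @param predictors predictors to prune.
#' @param vif_threshold keep-below threshold (default 10).
#' @return list `trajectory` (tibble `step`, `predictor`, `vif`, `dropped`),
#'   `retained`, `final_vif` (named vector, all < threshold).
#' @export
vif_prune <- function(stack, predictors = stack_predictors(stack),
                      vif_threshold = 10) {
  x <- as.data.frame(as_tibble(stack)[predictors])
  x <- x[complete.cases(x), , drop = FALSE]
  cur <- predictors
  traj <- list()
  step <- 0L
  repeat {
    if (length(cur) < 2) break
    vifs <- vapply(cur, function(p) {
      fit <- lm(stats::reformulate(cur[cur != p], response = p), data = x)
      r2 <- summary(fit)$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    step <- step + 1L
    if (all(vifs < vif_threshold)) {
      traj[[step]] <- tibble(step = step, predictor = names(vifs),
                             vif = unname(vifs), dropped = FALSE)
      break
    }
    worst <- names(vifs)[vifs == max(vifs)]
    worst <- sort(worst)[length(worst)]  # lexicographically last on ties
    traj[[step]] <- tibble(step = step, predictor = names(vifs),
                           vif = unname(vifs), dropped = names(vifs) == worst)
    cur <- setdiff(cur, worst)
  }
  final_vif <- if (length(cur) < 2) setNames(rep(1, length(cur)), cur) else {
    vapply(cur, function(p) {
      fit <- lm(stats::reformulate(cur[cur != p], response = p), data = x)
      1 / (1 - min(summary(fit)$r.squared, 1 - 1e-12))
    }, numeric(1))
  }
  list(trajectory = bind_rows(traj), retained = cur, final_vif = final_vif,
       vif_threshold = vif_threshold)
}

#' Correlation clustering followed by VIF pruning
#'
#' The full predictor-reduction procedure: cluster at `|r| >= r_threshold`,
#' keep one representative per cluster, then prune representatives by
#' stepwise VIF.
#'
#' @inheritParams correlation_clusters
#' @inheritParams vif_prune
#' @return a `predictor_selection` with the clustering fields plus
#'   `vif` (the [vif_prune()] result) and `retained` updated to the final
#'   predictor list.
#' @export
select_predictors <- function(stack, predictors = stack_predictors(stack),
                              r_threshold = 0.7, linkage = "average",
                              priority = NULL, vif_threshold = 10) {
  sel <- correlation_clusters(stack, predictors, r_threshold, linkage, priority)
  sel$vif <- if (length(sel$retained) >= 2)
    vif_prune(stack, sel$retained, vif_threshold)
  else list(trajectory = tibble(), retained = sel$retained,
            final_vif = setNames(rep(1, length(sel$retained)), sel$retained))
  sel$cluster_retained <- sel$retained
  sel$retained <- sel$vif$retained
  sel
}

#' @export
print.predictor_selection <- function(x, ...) {
  cat("<predictor_selection>\n")
  cat(sprintf("  clusters at |r| >= %.2f: %d\n", x$r_threshold,
              max(x$clusters$cluster)))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy predictor_selection
#' @export
tidy.predictor_selection <- function(x, ...) {
  out <- x$clusters
  out$retained <- out$predictor %in% x$retained
  if (!is.null(x$vif) && length(x$vif$final_vif))
    out$vif <- unname(x$vif$final_vif[out$predictor])
  out
}
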