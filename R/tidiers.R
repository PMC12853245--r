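#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an SDM ensemble
#'
#' One row per attempted ensemble member, with design coordinates
#' (learner, replicate, repetition, fold), stage-wise AUC, evaluation TSS,
#' and the retention flag.
#'
#' @param x an `sdm_ensemble`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy sdm_ensemble
#' @export
tidy.sdm_ensemble <- function(x, ...) {
  mutate(x$scores, species_id = x$species_id, .before = 1)
}

#' Glance at an SDM ensemble
#'
#' @param x an `sdm_ensemble`.
#' @param ... unused.
#' @return one-row tibble: species, attempted/retained member counts,
#'   ensemble training and evaluation AUC/TSS, Boyce index, binarization
#'   threshold, usability flag.
#' @method glance sdm_ensemble
#' @export
glance.sdm_ensemble <- function(x, ...) {
  ev <- if (!is.null(x$ensemble_scores))
    filter(x$ensemble_scores, .data$stage == "evaluation") else NULL
  tr <- if (!is.null(x$ensemble_scores))
    filter(x$ensemble_scores, .data$stage == "training") else NULL
  tibble(species_id = x$species_id,
         n_attempted = nrow(x$scores),
         n_retained = length(x$retained),
         auc_training = tr$auc %||% NA_real_,
         auc_evaluation = ev$auc %||% NA_real_,
         tss_evaluation = ev$tss %||% NA_real_,
         boyce = as.numeric(x$boyce),
         threshold = x$threshold,
         usable = x$usable)
}

#' Grid heatmap of a stack layer
#'
#' @param object an [env_stack()].
#' @param var layer to draw (default `T_median` if present, else depth).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot env_stack
#' @export
autoplot.env_stack <- function(object,
                               var = if ("T_median" %in% names(object)) "T_median" else "depth",
                               ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data[[var]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = var,
                  title = sprintf("%s (%s)", var, attr(object, "provenance"))) +
    ggplot2::theme_minimal()
}

#' Member evaluation AUC by learner
#'
#' @param object an `sdm_ensemble`.
#' @param ... unused.
#' @return a ggplot: per-learner boxplots of member evaluation AUC with the
#'   retention threshold drawn.
#' @method autoplot sdm_ensemble
#' @export
autoplot.sdm_ensemble <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$learner, y = .data$auc_evaluation)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$auc_min, linetype = 2) +
    ggplot2::labs(x = NULL, y = "evaluation AUC", title = object$species_id) +
    ggplot2::theme_minimal()
}

#' Hotspot class map
#'
#' @param object a `hotspot_grid`.
#' @param ... unused.
#' @return a ggplot raster of hotspot classes with turnover hotspots
#'   outlined as points.
#' @method autoplot hotspot_grid
#' @export
autoplot.hotspot_grid <- function(object, ...) {
  tb <- as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
    ggplot2::geom_point(data = filter(tb, .data$turnover_hotspot),
                        shape = ".", colour = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Shift-metric distributions across species
#'
#' @param shift_table the `shift_table` of a [run_pipeline()] result.
#' @param metric one of `dRANGE`, `dLAT`, `dDEPTH`, `dFRAG`.
#' @return a ggplot histogram faceted by scenario.
#' @export
plot_shift_distribution <- function(shift_table, metric = "dRANGE") {
  ggplot2::ggplot(shift_table, ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = 15) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = metric, y = "species") +
    ggplot2::theme_minimal()
}
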