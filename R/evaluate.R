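#' Rank-based AUC
#'
#' Area under the ROC curve by the rank statistic (midranks for ties):
#' the probability a random presence outscores a random absence, counting
#' ties as half.
#'
#' @param pred numeric suitability predictions.
#' @param labels 0/1 presence labels.
#' @return AUC in \[0, 1\], or `NA` when one class is absent.
#' @export
auc_score <- function(pred, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(pred, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximised true skill statistic
#'
#' TSS = sensitivity + specificity - 1, maximised over all candidate
#' thresholds (the unique predicted values). Returns the maximum and the
#' threshold attaining it (the smallest such threshold on ties).
#'
#' @inheritParams auc_score
#' @return list `tss`, `threshold`, or both `NA` when one class is absent.
#' @export
tss_max <- function(pred, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(list(tss = NA_real_, threshold = NA_real_))
  ord <- order(pred)
  p <- pred[ord]; y <- labels[ord]
  thr <- unique(p)
  # predictions >= threshold are presences
  idx <- findInterval(thr, p, left.open = TRUE)  # count of pred < thr
  cum1 <- cumsum(y); cum0 <- cumsum(1 - y)
  below1 <- ifelse(idx == 0, 0, cum1[pmax(idx, 1)]) * (idx > 0)
  below0 <- ifelse(idx == 0, 0, cum0[pmax(idx, 1)]) * (idx > 0)
  sens <- (n1 - below1) / n1
  spec <- below0 / n0
  tss <- sens + spec - 1
  best <- which.max(tss)
  list(tss = tss[best], threshold = thr[best])
}

#' AUC and TSS for one prediction set
#'
#' @inheritParams auc_score
#' @param stage label recorded alongside the scores
#'   (calibration / validation / evaluation).
#' @return one-row tibble `stage`, `auc`, `tss`, `tss_threshold`, `n_pres`,
#'   `n_abs`.
#' @export
score_predictions <- function(pred, labels, stage = "evaluation") {
  ts <- tss_max(pred, labels)
  tibble(stage = stage, auc = auc_score(pred, labels),
         tss = ts$tss, tss_threshold = ts$threshold,
         n_pres = sum(labels == 1), n_abs = sum(labels == 0))
}

#' Continuous Boyce index
#'
#' Presence-only evaluation: 100 moving windows of width one tenth of the
#' suitability range slide over \[min, max\] of the background suitability;
#' per window the predicted-to-expected ratio P/E compares the fraction of
#' presences to the fraction of background cells falling inside; the index
#' is the Spearman correlation between P/E and the window midpoint. A good
#' model yields monotonically increasing P/E (index near +1).
#'
#' @param suit_presence suitability at presence cells (>= 20 recommended).
#' @param suit_background suitability over the background (all sea cells).
#' @param n_windows number of windows (100).
#' @param width_frac window width as a fraction of the suitability range.
#' @return Boyce index in \[-1, 1\], or `NA` with attribute
#'   `undefined = TRUE` when the suitability range is degenerate.
#' @export
boyce_index <- function(suit_presence, suit_background,
                        n_windows = 100, width_frac = 0.1) {
  rng <- range(suit_background, finite = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  w <- diff(rng) * width_frac
  starts <- seq(rng[1], rng[2] - w, length.out = n_windows)
  mids <- starts + w / 2
  pe <- vapply(starts, function(s) {
    p <- mean(suit_presence >= s & suit_presence <= s + w)
    e <- mean(suit_background >= s & suit_background <= s + w)
    if (e == 0) NA_real_ else p / e
  }, numeric(1))
  ok <- !is.na(pe)
  if (sum(ok) < 3 || sd(pe[ok]) == 0) return(structure(NA_real_, undefined = TRUE))
  suppressWarnings(cor(pe[ok], mids[ok], method = "spearman"))
}
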