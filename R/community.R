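#' Stacked alpha diversity
#'
#' Per-cell sum of continuous habitat suitabilities across species — the
#' stacked-SDM estimate of expected richness.
#'
#' @param maps list of suitability maps ([project_ensemble()]) on one
#'   common grid.
#' @return tibble `cell`, `row`, `col`, `alpha`.
#' @export
alpha_stack <- function(maps) {
  if (!length(maps)) abort("alpha_stack: empty species list")
  base <- select(as_tibble(maps[[1]]), "cell", "row", "col")
  a <- numeric(nrow(base))
  for (m in maps) {
    if (!identical(m$cell, base$cell)) {
      idx <- match(base$cell, m$cell)
      if (anyNA(idx)) abort("alpha_stack: maps are not congruent")
      a <- a + m$suitability[idx]
    } else a <- a + m$suitability
  }
  mutate(base, alpha = a)
}

#' Alpha-diversity change
#'
#' Cellwise difference between future and baseline alpha diversity.
#'
#' @param alpha_future,alpha_baseline tibbles from [alpha_stack()].
#' @return tibble `cell`, `row`, `col`, `delta_alpha`.
#' @export
delta_alpha <- function(alpha_future, alpha_baseline) {
  out <- inner_join(rename(alpha_future, af = "alpha"),
                    select(rename(alpha_baseline, ab = "alpha"), "cell", "ab"),
                    by = "cell")
  if (nrow(out) != nrow(alpha_future)) abort("delta_alpha: grids not congruent")
  mutate(out, delta_alpha = .data$af - .data$ab) |>
    select("cell", "row", "col", "delta_alpha")
}

#' Temporal beta diversity with Podani decomposition
#'
#' Compares each cell's current and future predicted species sets with the
#' Jaccard family. With `a` species shared, `b` only current and `c` only
#' future: total dissimilarity `beta_tot = (b + c) / (a + b + c)`,
#' replacement (turnover) `beta_tu = 2 min(b, c) / (a + b + c)`, richness
#' difference (nestedness) `beta_ne = |b - c| / (a + b + c)` — the Podani
#' decomposition, with `beta_tu + beta_ne = beta_tot` exactly — and
#' `beta_ratio = beta_ne / beta_tot` (1 = pure richness difference, 0 =
#' pure replacement). Cells empty in both periods are undefined throughout;
#' cells with `beta_tot = 0` have `beta_ratio` undefined.
#'
#' @param current,future named lists (same species names, same order not
#'   required) of binary ranges, one per species.
#' @param stack the common grid.
#' @return tibble `cell`, `row`, `col`, `a`, `b`, `c`, `beta_tot`,
#'   `beta_tu`, `beta_ne`, `beta_ratio` (NA where undefined).
#' @export
temporal_beta <- function(current, future, stack) {
  sp <- sort(names(current))
  if (!identical(sp, sort(names(future))))
    abort("temporal_beta: species lists differ between periods")
  n <- nrow(stack)
  cur_n <- integer(n); fut_n <- integer(n); both <- integer(n)
  for (s in sp) {
    pc <- stack$cell %in% current[[s]]$cell
    pf <- stack$cell %in% future[[s]]$cell
    cur_n <- cur_n + pc
    fut_n <- fut_n + pf
    both <- both + (pc & pf)
  }
  a <- both; b <- cur_n - both; cc <- fut_n - both
  tot <- a + b + cc
  beta_tot <- ifelse(tot == 0, NA_real_, (b + cc) / tot)
  beta_tu <- ifelse(tot == 0, NA_real_, 2 * pmin(b, cc) / tot)
  beta_ne <- ifelse(tot == 0, NA_real_, abs(b - cc) / tot)
  beta_ratio <- ifelse(is.na(beta_tot) | beta_tot == 0, NA_real_,
                       beta_ne / beta_tot)
  tibble(cell = stack$cell, row = stack$row, col = stack$col,
         a = a, b = b, c = cc,
         beta_tot = beta_tot, beta_tu = beta_tu, beta_ne = beta_ne,
         beta_ratio = beta_ratio)
}
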