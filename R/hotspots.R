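#' Getis-Ord Gi* local spatial association
#'
#' For each non-missing cell, the neighbourhood is the cell itself plus its
#' `k` nearest non-missing cells by centroid distance (binary weights —
#' the self-inclusive Gi* statistic). The z-score is
#' `(sum_j w_ij x_j - xbar W) / (S sqrt((n W - W^2) / (n - 1)))`
#' with `xbar`, `S` the global mean and standard deviation over the `n`
#' non-missing cells and `W = k + 1` the weight sum. A zero-variance field
#' is degenerate: all z are NA and the result is flagged.
#'
#' @param values tibble `cell`, `row`, `col`, `value` (NA values are
#'   excluded from neighbourhoods and get no score).
#' @param k_neighbors neighbours per cell (24).
#' @return tibble `cell`, `row`, `col`, `z` with attribute
#'   `degenerate` (TRUE when the field has zero variance).
#' @export
getis_gstar <- function(values, k_neighbors = 24) {
  ok <- !is.na(values$value)
  x <- values$value[ok]
  n <- length(x)
  if (n < k_neighbors + 1)
    abort("getis_gstar: need at least k + 1 non-missing cells")
  out <- tibble(cell = values$cell, row = values$row, col = values$col,
                z = NA_real_)
  if (sd(x) == 0) {
    warn("getis_gstar: zero-variance field; degenerate")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  xbar <- mean(x); s <- sqrt(mean(x^2) - xbar^2)  # population sd, per Gi*
  W <- k_neighbors + 1
  denom <- s * sqrt((n * W - W^2) / (n - 1))
  rows <- values$row[ok]; cols <- values$col[ok]
  z <- numeric(n)
  chunk <- 500L
  for (i0 in seq(1, n, by = chunk)) {
    j <- seq(i0, min(i0 + chunk - 1L, n))
    d2 <- outer(rows[j], rows, "-")^2 + outer(cols[j], cols, "-")^2
    # k nearest plus self: self has d2 = 0 and is always included
    for (t in seq_along(j)) {
      dt <- d2[t, ]
      thr <- sort(dt, partial = W)[W]
      cand <- which(dt <= thr)
      nb <- cand[order(dt[cand])][seq_len(W)]  # stable: ties by cell order
      z[j[t]] <- (sum(x[nb]) - xbar * W) / denom
    }
  }
  out$z[ok] <- z
  attr(out, "degenerate") <- FALSE
  out
}

#' Classify community-change hotspots
#'
#' Combines Gi* z-score grids into the hotspot classes: cells where the
#' Gi* of delta-alpha is significantly high (low) are alpha increase
#' (decrease) hotspots; among the remaining cells, those where the Gi* of
#' |delta-alpha| is significantly low are stability spots ("coldspots" of
#' change); an independent boolean layer flags turnover hotspots where the
#' Gi* of beta_tu is significantly high (overlap with the classes is
#' allowed). Significance is two-sided at `alpha_level` per tail
#' (z* = |qnorm(alpha_level / 2)|, about 3.29 at the default 0.001).
#'
#' @param z_dalpha,z_absdalpha,z_turnover Gi* tibbles ([getis_gstar()]) on
#'   congruent cells.
#' @param alpha_level per-tail significance level (0.001).
#' @return a `hotspot_grid` tibble `cell`, `row`, `col`, `class`
#'   (`alpha_increase_hotspot` / `alpha_decrease_hotspot` /
#'   `stability_spot` / `none`), `turnover_hotspot` (logical), with
#'   attributes `z_star`, `alpha_level`.
#' @export
classify_hotspots <- function(z_dalpha, z_absdalpha, z_turnover,
                              alpha_level = 0.001) {
  stopifnot(identical(z_dalpha$cell, z_absdalpha$cell),
            identical(z_dalpha$cell, z_turnover$cell))
  zs <- abs(qnorm(alpha_level / 2))
  cls <- dplyr::case_when(
    !is.na(z_dalpha$z) & z_dalpha$z > zs ~ "alpha_increase_hotspot",
    !is.na(z_dalpha$z) & z_dalpha$z < -zs ~ "alpha_decrease_hotspot",
    !is.na(z_absdalpha$z) & z_absdalpha$z < -zs ~ "stability_spot",
    TRUE ~ "none")
  out <- tibble(cell = z_dalpha$cell, row = z_dalpha$row, col = z_dalpha$col,
                class = cls,
                turnover_hotspot = !is.na(z_turnover$z) & z_turnover$z > zs)
  structure(out, z_star = zs, alpha_level = alpha_level,
            class = c("hotspot_grid", class(tibble())))
}

#' @export
print.hotspot_grid <- function(x, ...) {
  cat(sprintf("<hotspot_grid> z* = %.3f\n", attr(x, "z_star")))
  print(count(as_tibble(x), .data$class, .data$turnover_hotspot))
  invisible(x)
}

#' Morphological core of a turnover region
#'
#' Benchmarking helper: given per-cell turnover values, returns the cells
#' belonging to the interior ("core") of contiguous high-turnover patches —
#' cells above `threshold` whose surrounding window is predominantly above
#' it too. Neighbourhood statistics such as Gi* identify clusters, so
#' recovery of a constructed turnover band is sensibly scored against the
#' band's core rather than its one-cell edge fringe.
#'
#' @param beta tibble with `cell`, `row`, `col` and a turnover column.
#' @param dims grid dimensions `c(rows, cols)`.
#' @param column turnover column name (`"beta_tu"`).
#' @param threshold cell-level turnover cut (0.5).
#' @param window half-width of the square neighbourhood (2 gives 5 x 5,
#'   matching a 24-neighbour cluster statistic).
#' @param min_count minimum above-threshold cells in the window (18 of 25).
#' @return logical vector along `beta` rows: TRUE for core cells.
#' @export
turnover_core <- function(beta, dims, column = "beta_tu", threshold = 0.5,
                          window = 2, min_count = 18) {
  v <- beta[[column]]
  hi <- !is.na(v) & v >= threshold
  m <- matrix(FALSE, dims[1], dims[2])
  m[cbind(beta$row[hi], beta$col[hi])] <- TRUE
  cnt <- matrix(0L, dims[1], dims[2])
  for (dr in -window:window) for (dc in -window:window) {
    rr <- pmax(pmin(row(m) + dr, dims[1]), 1L)
    cc <- pmax(pmin(col(m) + dc, dims[2]), 1L)
    cnt <- cnt + m[cbind(as.vector(rr), as.vector(cc))]
  }
  hi & (m & cnt >= min_count)[cbind(beta$row, beta$col)]
}
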