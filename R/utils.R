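# Internal helpers shared across the pipeline.

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols n across rename
#'   distinct count pull row_number slice
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 imap pmap keep
#' @importFrom stats median quantile cor cor.test sd qnorm plogis rnorm runif
#'   predict lm coef complete.cases setNames aggregate ecdf
NULL

# Deterministic child seeds: every stage derives its RNG stream from the
# master seed plus a string key, so one seed reproduces the whole run.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# cell id <-> (row, col) on an nr x nc grid, row-major, 1-based
cell_id <- function(row, col, dims) (row - 1L) * dims[2] + col
cell_row <- function(cell, dims) (cell - 1L) %/% dims[2] + 1L
cell_col <- function(cell, dims) (cell - 1L) %% dims[2] + 1L

# Gaussian-smoothed standard-normal random field on an nr x nc grid.
# Separable kernel convolution with edge renormalisation, then rescaled
# to zero mean / unit sd so `sd` multipliers mean what they say.
smooth_field <- function(dims, range = 5) {
  nr <- dims[1]; nc <- dims[2]
  z <- matrix(rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(2.5 * range))
  k <- exp(-(seq(-half, half))^2 / (2 * range^2))
  k <- k / sum(k)
  sm_dim <- function(m) {
    # convolve columns of m with k, renormalising at the edges
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + k[j]
    }
    out / wsum
  }
  z <- sm_dim(z)
  z <- t(sm_dim(t(z)))
  (z - mean(z)) / sd(z)
}

# clamp to [lo, hi]
clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ ".",
    TRUE ~ ""
  )
}
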