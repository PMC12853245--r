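#' Target-group kernel sampling intensity
#'
#' Gaussian-kernel smoothing of pooled target-group occurrences over sea
#' cells, truncated at the land/sea mask with boundary correction (each
#' cell's kernel sum is divided by the kernel mass falling on sea cells,
#' so coasts and grid edges are not artificially deflated), normalised to
#' sum 1. Used to draw pseudo-absences with the same spatial distribution
#' as survey effort, cancelling coastal sampling bias. With occurrences on
#' every sea cell the corrected intensity is exactly uniform.
#'
#' @param occurrences pooled occurrence tibble (`cell`, `row`, `col`) of the
#'   target group.
#' @param stack an [env_stack()].
#' @param bandwidth kernel standard deviation in cell units; default is a
#'   Silverman-style rule on the occurrence coordinates.
#' @return tibble `cell`, `intensity` over sea cells, summing to 1.
#' @export
density_kernel <- function(occurrences, stack, bandwidth = NULL) {
  if (nrow(occurrences) < 1) abort("density_kernel: need >= 1 occurrence")
  if (is.null(bandwidth))
    bandwidth <- max(1, mean(c(stats::bw.nrd0(occurrences$row + 0),
                               stats::bw.nrd0(occurrences$col + 0))))
  if (bandwidth <= 0) abort("density_kernel: bandwidth must be > 0")
  # pool duplicate occurrence cells into counts
  occ <- count(occurrences, .data$row, .data$col, name = "w")
  inten <- numeric(nrow(stack))
  chunk <- 1000L
  for (i in seq(1, nrow(stack), by = chunk)) {
    j <- seq(i, min(i + chunk - 1L, nrow(stack)))
    d2 <- outer(stack$row[j], occ$row, "-")^2 + outer(stack$col[j], occ$col, "-")^2
    num <- as.numeric(exp(-d2 / (2 * bandwidth^2)) %*% occ$w)
    # boundary correction: kernel mass available on sea cells around j
    d2m <- outer(stack$row[j], stack$row, "-")^2 + outer(stack$col[j], stack$col, "-")^2
    mass <- rowSums(exp(-d2m / (2 * bandwidth^2)))
    inten[j] <- num / mass
  }
  tibble(cell = stack$cell, intensity = inten / sum(inten))
}

#' Draw density-dependent pseudo-absences
#'
#' Samples cells without replacement with probability proportional to a
#' sampling-effort intensity, excluding the focal species' presence cells.
#'
#' @param intensity tibble `cell`, `intensity` (from [density_kernel()]).
#' @param n number of pseudo-absences.
#' @param exclude_cells presence cells of the focal species.
#' @param seed integer seed.
#' @return integer vector of sampled cell ids.
#' @export
sample_density_pa <- function(intensity, n, exclude_cells = integer(), seed = 1) {
  if (n < 1) abort("sample_density_pa: n must be >= 1")
  elig <- filter(intensity, !.data$cell %in% exclude_cells, .data$intensity > 0)
  if (nrow(elig) == 0) {
    warn("sample_density_pa: no eligible cell; returning empty")
    return(integer())
  }
  if (nrow(elig) <= n) {
    if (nrow(elig) < n)
      warn(sprintf("sample_density_pa: only %d eligible cells (< n = %d)", nrow(elig), n))
    return(sort(elig$cell))
  }
  with_seed(derive_seed(seed, "density_pa"),
            sort(sample(elig$cell, n, replace = FALSE, prob = elig$intensity)))
}

#' Draw environmentally stratified pseudo-absences
#'
#' Bins median temperature and median salinity into three classes each at
#' their 0.3 and 0.6 quantiles over sea cells (lower-closed, upper-open bin
#' edges), crosses them into up to nine strata, and samples an equal number
#' of pseudo-absences per stratum, uniformly within stratum, excluding the
#' focal presences. Remainders, and the quotas of empty or exhausted
#' strata, are redistributed over the remaining strata proportionally to
#' their eligible-cell counts (fixed stratum order for the rounding).
#'
#' @param stack an [env_stack()] with `T_median` and `SAL_median`.
#' @param n total pseudo-absences.
#' @param exclude_cells focal presence cells.
#' @param seed integer seed.
#' @return integer vector of sampled cell ids, with a `strata` attribute:
#'   tibble `stratum`, `n_cells`, `quota`, `sampled`.
#' @export
sample_stratified_pa <- function(stack, n, exclude_cells = integer(), seed = 1) {
  if (n < 1) abort("sample_stratified_pa: n must be >= 1")
  need <- c("T_median", "SAL_median")
  if (!all(need %in% names(stack)))
    abort("sample_stratified_pa: stack must carry T_median and SAL_median")
  bin3 <- function(v, nm) {
    q <- quantile(v, c(0.3, 0.6), names = FALSE)
    if (q[1] == q[2]) {
      warn(sprintf("sample_stratified_pa: %s quantiles collapse; bins merged", nm))
    }
    1L + (v >= q[1]) + (v >= q[2])
  }
  tb <- bin3(stack$T_median, "T_median")
  sb <- bin3(stack$SAL_median, "SAL_median")
  stratum <- paste0("T", tb, "_S", sb)
  elig <- tibble(cell = stack$cell, stratum = stratum) |>
    filter(!.data$cell %in% exclude_cells)
  levels_all <- sort(unique(stratum))
  counts <- vapply(levels_all, function(s) sum(elig$stratum == s), integer(1))
  # proportional redistribution with fixed-order rounding until all quota
  # is placed or eligibility is exhausted
  quota <- setNames(integer(length(levels_all)), levels_all)
  remaining <- n
  open <- levels_all[counts > 0]
  while (remaining > 0 && length(open) > 0) {
    cap <- counts[open] - quota[open]
    open <- open[cap > 0]; if (!length(open)) break
    cap <- counts[open] - quota[open]
    base <- floor(remaining / length(open))
    add <- pmin(cap, base)
    # spread the remainder over strata in fixed (sorted) order
    rem <- remaining - sum(add)
    i <- 1L
    while (rem > 0 && i <= length(open)) {
      if (add[i] < cap[i]) { add[i] <- add[i] + 1L; rem <- rem - 1L }
      i <- i + 1L
    }
    quota[open] <- quota[open] + add
    remaining <- remaining - sum(add)
    if (all(add == 0)) break
  }
  if (remaining > 0)
    warn(sprintf("sample_stratified_pa: only %d eligible cells for n = %d", n - remaining, n))
  picks <- with_seed(derive_seed(seed, "stratified_pa"), {
    unlist(lapply(levels_all, function(s) {
      k <- quota[[s]]
      if (k == 0) return(integer())
      pool <- elig$cell[elig$stratum == s]
      if (k >= length(pool)) pool else sample(pool, k, replace = FALSE)
    }), use.names = FALSE)
  })
  out <- sort(picks)
  attr(out, "strata") <- tibble(stratum = levels_all, n_cells = unname(counts),
                                quota = unname(quota),
                                sampled = unname(quota))
  out
}

#' Replicated two-strategy pseudo-absence sets
#'
#' Builds `reps` pseudo-absence replicates, each combining the two
#' strategies: a `split` fraction drawn density-dependently from the
#' target-group effort kernel and the rest environmentally stratified
#' (defaults: 10000 points per replicate, half and half, three replicates).
#' Pseudo-absences never coincide with the focal species' presence cells.
#' Replicate seeds derive deterministically from `seed`.
#'
#' @param stack an [env_stack()].
#' @param focal_occurrences presence tibble of the focal species
#'   (`cell`, ...).
#' @param target_group pooled occurrence tibble of the target group used
#'   for the effort kernel (defaults to the focal occurrences).
#' @param n_total points per replicate.
#' @param split fraction drawn by the density strategy.
#' @param reps number of replicates.
#' @param seed master seed.
#' @param bandwidth kernel bandwidth passed to [density_kernel()].
#' @return tibble `replicate`, `cell`, `row`, `col`, `strategy`
#'   (`"density"`/`"stratified"`).
#' @export
build_pa_replicates <- function(stack, focal_occurrences, target_group = NULL,
                                n_total = 10000, split = 0.5, reps = 3,
                                seed = 1, bandwidth = NULL) {
  if (is.null(target_group)) target_group <- focal_occurrences
  intensity <- density_kernel(target_group, stack, bandwidth = bandwidth)
  excl <- unique(focal_occurrences$cell)
  n_dens <- round(n_total * split)
  n_strat <- n_total - n_dens
  d <- stack_dims(stack)
  out <- purrr::map(seq_len(reps), function(r) {
    rs <- derive_seed(seed, paste0("pa_rep_", r))
    dens <- sample_density_pa(intensity, n_dens, excl, seed = rs)
    strat <- sample_stratified_pa(stack, n_strat, excl, seed = rs + 1L)
    tibble(replicate = r,
           cell = c(dens, as.integer(strat)),
           strategy = rep(c("density", "stratified"), c(length(dens), length(strat))))
  }) |> bind_rows()
  out$row <- cell_row(out$cell, d)
  out$col <- cell_col(out$cell, d)
  select(out, "replicate", "cell", "row", "col", "strategy")
}
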