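#' Growth selection parameters
#'
#' Growth/survival screens compare a population sampled at the start of the
#' screen (t0) with the population after `num_passages` rounds of growth
#' and passaging (tn). Each passage is one timestep in which wild-type
#' cells double, followed by a bottleneck that subsamples the pool back to
#' `representation * n_guides` cells.
#'
#' @param num_passages Number of growth-and-passage rounds (`n >= 1`).
#' @param representation Cells per guide retained at each bottleneck.
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(num_passages = 3, representation = 100) {
  if (num_passages < 1) stop("num_passages must be >= 1")
  if (representation < 1) stop("representation must be >= 1")
  structure(list(num_passages = as.integer(num_passages),
                 representation = representation), class = "growth_params")
}

# One growth timestep. In the time a wild-type cell divides once, a cell
# with phenotype phi > 0 behaves like a maximal-phenotype cell (divides
# twice -> 4 cells) with probability phi and like wild type (-> 2 cells)
# otherwise; a cell with phi < 0 does not divide (-> 1 cell) with
# probability |phi|. Realised per bucket as a binomial count of
# extreme-behaviour cells, which is distributionally identical to the
# per-cell rule.
grow_step <- function(pool) {
  c0 <- pool$cells
  phi <- pool$phenotype
  extreme <- stats::rbinom(length(c0), c0, abs(phi))
  newc <- ifelse(phi > 0, 4 * extreme + 2 * (c0 - extreme),
                 ifelse(phi < 0, extreme + 2 * (c0 - extreme), 2 * c0))
  new_cell_pool(pool$guide_id, pool$knockdown, pool$phenotype, newc,
                attr(pool, "n_guides"), attr(pool, "n_initial"))
}

#' Run a growth screen's selection phase
#'
#' Subsamples the post-infection pool to the bottleneck size to form the t0
#' comparison population, then alternates growth timesteps and bottleneck
#' subsampling `num_passages` times; the pool after the final subsample is
#' the tn population. The expected per-timestep growth factor of a bucket
#' with phenotype `phi` is `2 + 2*phi` for `phi >= 0` and `2 - |phi|` for
#' `phi < 0`.
#'
#' @param pool A cell pool from [infect()].
#' @param params A [growth_params()].
#' @return A list with elements `t0` and `tn`, each a cell pool.
#' @export
grow_pool <- function(pool, params = growth_params()) {
  stopifnot(inherits(params, "growth_params"))
  if (nrow(pool) == 0 || pool_size(pool) == 0) stop("pool must be nonempty")
  bottleneck <- params$representation * attr(pool, "n_guides")
  t0 <- subsample_pool(pool, bottleneck)
  current <- t0
  for (i in seq_len(params$num_passages)) {
    current <- subsample_pool(grow_step(current), bottleneck)
  }
  list(t0 = t0, tn = current)
}
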