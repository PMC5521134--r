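#' FACS selection parameters
#'
#' FACS sorting compares the cells with the lowest and highest observed
#' reporter signal. Before sorting, the pool is bottlenecked to
#' `representation * n_guides` cells. Each cell's observed phenotype is its
#' theoretical phenotype convolved with zero-mean Gaussian noise of
#' standard deviation `noise_sigma` (biological variance in fluorescence of
#' isogenic cells). The bottom `bin_fraction` and top `bin_fraction` of
#' cells by observed phenotype form the two comparison bins.
#'
#' @param bin_fraction Fraction of cells in each tail bin, in (0, 0.5].
#' @param noise_sigma Standard deviation of the phenotype observation
#'   noise, in phenotype units (a gene with maximal phenotype 1 sits one
#'   noise SD away from wild type at the default of 1.0).
#' @param representation Cells per guide entering the sorter.
#' @return A list of class `facs_params`.
#' @export
facs_params <- function(bin_fraction = 0.25, noise_sigma = 1.0,
                        representation = 100) {
  if (!(bin_fraction > 0 && bin_fraction <= 0.5)) {
    stop("bin_fraction must lie in (0, 0.5]")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (representation < 1) stop("representation must be >= 1")
  structure(list(bin_fraction = bin_fraction, noise_sigma = noise_sigma,
                 representation = representation), class = "facs_params")
}

#' Sort a cell pool into low and high reporter bins
#'
#' Bottlenecks the pool to `representation * n_guides` cells by multinomial
#' resampling, draws each cell's observed phenotype (bucket phenotype plus
#' Gaussian noise), ranks all cells, and returns the lowest and highest
#' `bin_fraction` of cells as two pools. Each bin contains exactly
#' `round(bin_fraction * bottleneck)` cells; ties in observed phenotype
#' (which arise only when `noise_sigma = 0`) are broken in random order.
#'
#' @param pool A cell pool from [infect()].
#' @param params A [facs_params()].
#' @return A list with elements `low` and `high`, each a cell pool.
#' @export
facs_sort <- function(pool, params = facs_params()) {
  stopifnot(inherits(params, "facs_params"))
  if (nrow(pool) == 0 || pool_size(pool) == 0) stop("pool must be nonempty")
  n_guides <- attr(pool, "n_guides")
  bottleneck <- params$representation * n_guides
  pool <- subsample_pool(pool, bottleneck)

  counts <- pool$cells
  bucket <- rep.int(seq_len(nrow(pool)), counts)
  observed <- rep.int(pool$phenotype, counts) +
    stats::rnorm(bottleneck, 0, params$noise_sigma)
  per_bin <- round(params$bin_fraction * bottleneck)

  ord <- order(observed, stats::runif(bottleneck))
  low_idx <- ord[seq_len(per_bin)]
  high_idx <- ord[seq.int(bottleneck - per_bin + 1, bottleneck)]

  bin_pool <- function(idx) {
    cnt <- tabulate(bucket[idx], nbins = nrow(pool))
    new_cell_pool(pool$guide_id, pool$knockdown, pool$phenotype, cnt,
                  n_guides, attr(pool, "n_initial"))
  }
  list(low = bin_pool(low_idx), high = bin_pool(high_idx))
}
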