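#' Infection parameters
#'
#' Lentiviral infection is modelled as a Poisson process: each cell of the
#' initial pool receives `Poisson(moi)` integrations, and only cells with
#' exactly one integration are carried forward (antibiotic/marker selection
#' for single-copy infection). At the default MOI of 0.25 the retained
#' fraction is `0.25 * exp(-0.25)`, about 19.5% of the initial pool.
#'
#' @param moi Multiplicity of infection, the expected integrations per cell.
#' @param representation Cells per library guide in the initial
#'   (pre-selection) pool; the pool size is `representation * n_guides`.
#' @return A list of class `infection_params`.
#' @export
infection_params <- function(moi = 0.25, representation = 100) {
  if (moi < 0) stop("moi must be >= 0")
  if (representation < 1) stop("representation must be >= 1")
  structure(list(moi = moi, representation = representation),
            class = "infection_params")
}

# CRISPRn knockout outcomes for a fully active guide: assuming 2/3 of
# repair events cause a frameshift in a diploid cell, a cell ends up with
# no functional knockout (both alleles in frame) w.p. 1/9, a monoallelic
# knockout (50% knockdown) w.p. 4/9, or a biallelic knockout (100%)
# w.p. 4/9.
crisprn_outcomes <- function() {
  list(knockdown = c(0, 0.5, 1), prob = c(1, 4, 4) / 9)
}

new_cell_pool <- function(guide_id, knockdown, phenotype, cells,
                          n_guides, n_initial = NA_real_) {
  keep <- cells > 0
  pool <- data.frame(guide_id = guide_id[keep],
                     knockdown = knockdown[keep],
                     phenotype = phenotype[keep],
                     cells = as.numeric(cells[keep]))
  attr(pool, "n_guides") <- n_guides
  attr(pool, "n_initial") <- n_initial
  class(pool) <- c("cell_pool", "data.frame")
  pool
}

#' Total number of cells in a pool
#'
#' @param pool A cell pool as returned by [infect()], [facs_sort()] or
#'   [grow_pool()].
#' @return The total cell count.
#' @export
pool_size <- function(pool) sum(pool$cells)

# multinomial subsample (with replacement) of a pool down to `size` cells
subsample_pool <- function(pool, size) {
  if (nrow(pool) == 0 || pool_size(pool) == 0) stop("cannot subsample an empty pool")
  counts <- as.numeric(stats::rmultinom(1, size, pool$cells))
  new_cell_pool(pool$guide_id, pool$knockdown, pool$phenotype, counts,
                attr(pool, "n_guides"), attr(pool, "n_initial"))
}

#' Infect a cell pool with the sgRNA library
#'
#' Simulates lentiviral infection of `representation * n_guides` cells at
#' the configured MOI, retains single-integrant cells, assigns each
#' retained cell a guide according to the plasmid frequencies, and realises
#' each cell's knockdown level. CRISPRi cells realise the guide's knockdown
#' efficiency directly. CRISPRn cells carrying a high-activity guide
#' realise a heritable knockout outcome of 0%, 50% or 100% knockdown with
#' probabilities 1/9, 4/9 and 4/9 (see [crisprn_outcomes()]); low-activity
#' CRISPRn guides behave like weak CRISPRi guides. The realised knockdown
#' is mapped to a cell phenotype through the gene's knockdown-response
#' function.
#'
#' Cells are tracked as counts per (guide, realised knockdown) bucket; all
#' cells in a bucket share the same phenotype, so this aggregation is
#' behaviourally identical to tracking cells individually.
#'
#' @param library Library data frame from [build_library()].
#' @param genome Genome data frame from [build_genome()].
#' @param params An [infection_params()].
#' @param mode `"CRISPRi"` or `"CRISPRn"`; defaults to the library's mode.
#' @return A cell pool: a data frame of buckets with columns `guide_id`,
#'   `knockdown`, `phenotype`, `cells`, plus attributes `n_guides` and
#'   `n_initial` (the pre-selection pool size).
#' @export
infect <- function(library, genome, params = infection_params(),
                   mode = attr(library, "mode")) {
  stopifnot(inherits(params, "infection_params"))
  if (is.null(library) || nrow(library) == 0) stop("library must be nonempty")
  if (is.null(mode)) mode <- "CRISPRi"
  mode <- match.arg(mode, c("CRISPRi", "CRISPRn"))

  n_guides <- nrow(library)
  n_initial <- params$representation * n_guides
  # number of single-integrant cells: each initial cell independently has
  # P(Poisson(moi) == 1) of being retained
  retained <- stats::rbinom(1, n_initial, stats::dpois(1, params$moi))

  if (retained == 0) {
    return(new_cell_pool(integer(0), numeric(0), numeric(0), numeric(0),
                         n_guides, n_initial))
  }
  per_guide <- as.numeric(stats::rmultinom(1, retained,
                                           library$plasmid_frequency))

  if (mode == "CRISPRi") {
    guide_id <- library$guide_id
    knockdown <- library$efficiency
    cells <- per_guide
  } else {
    active <- library$high_activity & library$efficiency >= 1
    out <- crisprn_outcomes()
    # split each active guide's cells over the three repair outcomes
    ca <- per_guide[active]
    n0 <- stats::rbinom(length(ca), ca, out$prob[1])
    n50 <- stats::rbinom(length(ca), ca - n0,
                         out$prob[2] / (out$prob[2] + out$prob[3]))
    n100 <- ca - n0 - n50
    guide_id <- c(rep(library$guide_id[active], 3), library$guide_id[!active])
    knockdown <- c(rep(out$knockdown, each = sum(active)),
                   library$efficiency[!active])
    cells <- c(n0, n50, n100, per_guide[!active])
  }

  gi <- match(library$gene_id[match(guide_id, library$guide_id)],
              genome$gene_id)
  phen <- cell_phenotype(knockdown, genome$true_phenotype[gi],
                         genome$response_kind[gi], genome$p[gi], genome$k[gi])
  new_cell_pool(guide_id, knockdown, phen, cells, n_guides, n_initial)
}
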