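#' Configuration for the sgRNA library
#'
#' Each gene is targeted by `guides_per_gene` independent sgRNAs. Guide
#' activity is bimodal: a `fraction_high_activity` share of guides is highly
#' active and the rest have low activity barely distinguishable from
#' controls. In CRISPRi mode high-activity guides draw their knockdown
#' efficiency from a Gaussian (default mean 0.90, sd 0.1); in CRISPRn mode
#' high-activity guides cut with maximal efficiency 1.0 and the realised
#' knockout per cell is decided later, at infection, by the stochastic DNA
#' repair outcome. Low-activity guides draw from a Gaussian with mean 0.05,
#' sd 0.07 in both modes. Efficiencies are clamped to \[0, 1\].
#'
#' Plasmid frequencies are log-normal, parameterised so that a guide at the
#' 95th percentile of frequency is `frequency_spread` times as frequent as
#' one at the 5th percentile, then normalised to sum to 1.
#'
#' @param guides_per_gene Number of sgRNAs per gene (`m`).
#' @param mode `"CRISPRi"` or `"CRISPRn"`.
#' @param fraction_high_activity Fraction of high-activity guides.
#' @param low_mean,low_sd Gaussian for low-activity knockdown efficiency.
#' @param high_mean,high_sd Gaussian for high-activity efficiency
#'   (CRISPRi only).
#' @param frequency_spread Ratio of the 95th- to 5th-percentile plasmid
#'   frequency; must be >= 1.
#' @return A list of class `library_config`.
#' @export
library_config <- function(guides_per_gene = 5,
                           mode = c("CRISPRi", "CRISPRn"),
                           fraction_high_activity = 0.9,
                           low_mean = 0.05, low_sd = 0.07,
                           high_mean = 0.90, high_sd = 0.1,
                           frequency_spread = 10) {
  mode <- match.arg(mode)
  stopifnot(guides_per_gene >= 1,
            fraction_high_activity >= 0, fraction_high_activity <= 1,
            frequency_spread >= 1)
  structure(list(
    guides_per_gene = as.integer(guides_per_gene),
    mode = mode,
    fraction_high_activity = fraction_high_activity,
    low_mean = low_mean, low_sd = low_sd,
    high_mean = high_mean, high_sd = high_sd,
    frequency_spread = frequency_spread
  ), class = "library_config")
}

#' Log-normal sigma matching a percentile ratio
#'
#' Solves for the log-scale standard deviation of a log-normal distribution
#' such that the ratio of its `upper_q` quantile to its `lower_q` quantile
#' equals `ratio`: `sigma = log(ratio) / (z(upper_q) - z(lower_q))` with `z`
#' the standard normal quantile function. The log-scale mean is irrelevant
#' here because library frequencies are normalised afterwards.
#'
#' @param ratio Target fold ratio between the two quantiles (>= 1).
#' @param lower_q,upper_q Quantile probabilities, `0 < lower_q < upper_q < 1`.
#' @return The log-scale standard deviation (0 when `ratio` is 1).
#' @examples
#' lognormal_sigma_for_ratio(10)  # ~0.6998
#' @export
lognormal_sigma_for_ratio <- function(ratio, lower_q = 0.05, upper_q = 0.95) {
  if (ratio < 1) stop("ratio must be >= 1")
  if (!(lower_q > 0 && lower_q < upper_q && upper_q < 1)) {
    stop("quantiles must satisfy 0 < lower_q < upper_q < 1")
  }
  log(ratio) / (stats::qnorm(upper_q) - stats::qnorm(lower_q))
}

#' Build an sgRNA library targeting a genome
#'
#' Draws per-guide knockdown efficiencies from the mode-specific activity
#' model and plasmid frequencies from the normalised log-normal model (see
#' [library_config()]). Guides cover the genome as an exact
#' `guides_per_gene`-to-1 map.
#'
#' @param genome Genome data frame from [build_genome()].
#' @param config A [library_config()].
#' @return A data frame with columns `guide_id`, `gene_id`,
#'   `high_activity` (logical), `efficiency` and `plasmid_frequency`
#'   (summing to 1), with the screen mode in attribute `"mode"`.
#' @examples
#' set.seed(1)
#' lib <- build_library(build_genome(genome_config(n_genes = 10)))
#' sum(lib$plasmid_frequency)
#' @export
build_library <- function(genome, config = library_config()) {
  stopifnot(inherits(config, "library_config"))
  if (is.null(genome) || nrow(genome) == 0) stop("genome must be nonempty")
  m <- config$guides_per_gene
  n_guides <- nrow(genome) * m

  high <- stats::runif(n_guides) < config$fraction_high_activity
  eff <- numeric(n_guides)
  eff[!high] <- stats::rnorm(sum(!high), config$low_mean, config$low_sd)
  if (config$mode == "CRISPRi") {
    eff[high] <- stats::rnorm(sum(high), config$high_mean, config$high_sd)
  } else {
    eff[high] <- 1.0  # nuclease guides cut at full efficiency
  }
  eff <- pmin(pmax(eff, 0), 1)

  sigma <- lognormal_sigma_for_ratio(config$frequency_spread)
  freq <- stats::rlnorm(n_guides, meanlog = 0, sdlog = sigma)
  freq <- freq / sum(freq)

  lib <- data.frame(
    guide_id = seq_len(n_guides),
    gene_id = rep(genome$gene_id, each = m),
    high_activity = high,
    efficiency = eff,
    plasmid_frequency = freq
  )
  attr(lib, "mode") <- config$mode
  lib
}

#' Write a library to a tab-delimited file
#'
#' @param library Library data frame from [build_library()].
#' @param path Output file path.
#' @export
write_library <- function(library, path) {
  write_tsv_impl(library, path)
}
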