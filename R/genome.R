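#' Configuration for the simulated genome
#'
#' A simulated genome assigns each of `n_genes` genes a class, a "true"
#' phenotype `l` and a knockdown-response function. Wild-type and
#' negative-control genes carry phenotype 0; hit genes draw their phenotype
#' from a clamped Gaussian. Each gene responds to knockdown either linearly
#' or through a switch-like sigmoid with inflection point `p` and half-width
#' `k` (both expressed as knockdown fractions).
#'
#' @param n_genes Number of genes in the genome.
#' @param class_fractions Named numeric vector of class fractions over
#'   `wildtype`, `negative_control`, `positive_hit`, `negative_hit`;
#'   must sum to 1. Class counts are assigned deterministically as
#'   `floor(n_genes * fraction)` with the remainder distributed in the
#'   order above.
#' @param positive_mean,positive_sd Gaussian parameters for positive-hit
#'   phenotypes before clamping.
#' @param positive_range Clamp interval for positive-hit phenotypes; draws
#'   outside are clipped to the boundary, not redrawn.
#' @param negative_mean,negative_sd,negative_range Same for negative hits.
#' @param fraction_sigmoidal Fraction of genes given a sigmoidal (rather
#'   than linear) knockdown-response function.
#' @param sigmoid_p_mean,sigmoid_p_sd Gaussian for the inflection point `p`;
#'   draws are rejected until `p` lies in \[0.05, 0.99\].
#' @param sigmoid_k_mean,sigmoid_k_sd Gaussian for the inflection half-width
#'   `k`; draws are rejected until `k >= 0.01`.
#'
#' @return A list of class `genome_config`.
#' @seealso [build_genome()]
#' @export
genome_config <- function(n_genes = 500,
                          class_fractions = c(wildtype = 0.75,
                                              negative_control = 0.05,
                                              positive_hit = 0.10,
                                              negative_hit = 0.10),
                          positive_mean = 0.55, positive_sd = 0.2,
                          positive_range = c(0.1, 1.0),
                          negative_mean = -0.55, negative_sd = 0.2,
                          negative_range = c(-1.0, -0.1),
                          fraction_sigmoidal = 0.25,
                          sigmoid_p_mean = 0.8, sigmoid_p_sd = 0.2,
                          sigmoid_k_mean = 0.1, sigmoid_k_sd = 0.05) {
  fr <- rep(0, 4)
  names(fr) <- gene_classes()
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% gene_classes())) {
    stop("class_fractions must be named with a subset of: ",
         paste(gene_classes(), collapse = ", "))
  }
  fr[names(class_fractions)] <- class_fractions
  if (abs(sum(fr) - 1) > 1e-8) {
    stop("class fractions must sum to 1 (got ", sum(fr), ")")
  }
  if (n_genes < 1) stop("n_genes must be >= 1")
  structure(list(
    n_genes = as.integer(n_genes),
    class_fractions = fr,
    positive_mean = positive_mean, positive_sd = positive_sd,
    positive_range = positive_range,
    negative_mean = negative_mean, negative_sd = negative_sd,
    negative_range = negative_range,
    fraction_sigmoidal = fraction_sigmoidal,
    sigmoid_p_mean = sigmoid_p_mean, sigmoid_p_sd = sigmoid_p_sd,
    sigmoid_k_mean = sigmoid_k_mean, sigmoid_k_sd = sigmoid_k_sd
  ), class = "genome_config")
}

gene_classes <- function() {
  c("wildtype", "negative_control", "positive_hit", "negative_hit")
}

#' Deterministic class counts for a genome
#'
#' Counts are `floor(n * fraction)` per class with the remaining genes
#' assigned one each to classes in the fixed order wildtype,
#' negative_control, positive_hit, negative_hit. The result depends only on
#' `(n, fractions)`, never on the random stream.
#'
#' @param n Number of genes.
#' @param fractions Named fractions over the four classes, summing to 1.
#' @return Named integer vector of per-class counts summing to `n`.
#' @export
class_counts <- function(n, fractions) {
  fractions <- fractions[gene_classes()]
  counts <- floor(n * fractions)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- rep_len(seq_along(counts), rem)
    counts[extra] <- counts[extra] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

# draw from a Gaussian and clip to [lo, hi] (censoring, not truncation)
rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# rejection-sample sigmoid parameters into their sane ranges
draw_sigmoid_params <- function(n, p_mean, p_sd, k_mean, k_sd) {
  draw_until <- function(n, mean, sd, ok) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(!ok(x))
    while (length(bad) > 0) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[!ok(x[bad])]
    }
    x
  }
  list(p = draw_until(n, p_mean, p_sd, function(x) x >= 0.05 & x <= 0.99),
       k = draw_until(n, k_mean, k_sd, function(x) x >= 0.01))
}

#' Generate a simulated genome
#'
#' Assigns each gene a class, a true phenotype and a knockdown-response
#' function according to a [genome_config()]. Uses the current R random
#' stream; call `set.seed()` beforehand for reproducibility. Class counts
#' are deterministic given the configuration (see [class_counts()]); only
#' phenotype values and response assignments are random.
#'
#' @param config A [genome_config()].
#' @return A data frame with one row per gene and columns `gene_id`,
#'   `class`, `true_phenotype`, `response_kind` (`"linear"` or
#'   `"sigmoidal"`), `p` and `k` (`NA` for linear genes).
#' @examples
#' set.seed(1)
#' g <- build_genome(genome_config(n_genes = 100))
#' table(g$class)
#' @export
build_genome <- function(config = genome_config()) {
  stopifnot(inherits(config, "genome_config"))
  n <- config$n_genes
  counts <- class_counts(n, config$class_fractions)
  cls <- rep(gene_classes(), counts)

  phen <- numeric(n)
  pos <- cls == "positive_hit"
  neg <- cls == "negative_hit"
  phen[pos] <- rnorm_clamped(sum(pos), config$positive_mean, config$positive_sd,
                             config$positive_range[1], config$positive_range[2])
  phen[neg] <- rnorm_clamped(sum(neg), config$negative_mean, config$negative_sd,
                             config$negative_range[1], config$negative_range[2])

  sig <- stats::runif(n) < config$fraction_sigmoidal
  p <- rep(NA_real_, n)
  k <- rep(NA_real_, n)
  if (any(sig)) {
    sp <- draw_sigmoid_params(sum(sig), config$sigmoid_p_mean,
                              config$sigmoid_p_sd, config$sigmoid_k_mean,
                              config$sigmoid_k_sd)
    p[sig] <- sp$p
    k[sig] <- sp$k
  }

  data.frame(
    gene_id = seq_len(n),
    class = cls,
    true_phenotype = phen,
    response_kind = ifelse(sig, "sigmoidal", "linear"),
    p = p,
    k = k,
    stringsAsFactors = FALSE
  )
}

#' Knockdown-response function
#'
#' Maps a knockdown fraction `x` in \[0, 1\] to the fraction of the gene's
#' full phenotype that is realised. Linear genes interpolate linearly
#' between 0 (no knockdown) and 1 (full knockdown), i.e. `f(x) = x`.
#' Sigmoidal genes are switch-like around the inflection point `p` with
#' half-width `k`:
#' \deqn{f(x) = 0 \;(x \le p-k);\quad 1 \;(x \ge p+k);\quad
#'   \tfrac{1}{2}\left(\frac{\mathrm{sign}(\delta)\,1.05|\delta|}{|\delta|+1}
#'   + 1\right) \text{ otherwise}}
#' with \eqn{\delta = (x - p) / \min(p, \min(1-p, k))}. `sign(0) = 0`, so
#' `f(p) = 0.5` exactly. The function is applied as printed, including its
#' jump discontinuities at `x = p - k` and `x = p + k`.
#'
#' All arguments are vectorised and recycled against each other.
#'
#' @param x Knockdown fraction(s) in \[0, 1\].
#' @param kind `"linear"` or `"sigmoidal"` (vectorised).
#' @param p,k Sigmoid parameters (ignored for linear entries).
#' @return Response fraction(s) in \[0, 1\].
#' @examples
#' response_fraction(0.8, "sigmoidal", p = 0.8, k = 0.1)  # 0.5 at inflection
#' response_fraction(c(0, 0.5, 1), "linear")
#' @export
response_fraction <- function(x, kind, p = NA_real_, k = NA_real_) {
  n <- max(length(x), length(kind), length(p), length(k))
  x <- rep_len(x, n)
  kind <- rep_len(kind, n)
  p <- rep_len(p, n)
  k <- rep_len(k, n)
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("knockdown fraction x must lie in [0, 1]")
  }
  out <- x  # linear default
  s <- which(kind == "sigmoidal")
  if (length(s) > 0) {
    xs <- x[s]; ps <- p[s]; ks <- k[s]
    delta <- (xs - ps) / pmin(ps, pmin(1 - ps, ks))
    mid <- 0.5 * (sign(delta) * 1.05 * abs(delta) / (abs(delta) + 1) + 1)
    # the response is a fraction of the full phenotype: when the window
    # half-width k exceeds min(p, 1-p) the raw expression can leave [0, 1]
    # near the window edges (|delta| > 20), so clip it to its nominal range
    mid <- pmin(pmax(mid, 0), 1)
    f <- ifelse(xs <= ps - ks, 0, ifelse(xs >= ps + ks, 1, mid))
    out[s] <- f
  }
  out
}

#' Cell phenotype at a realised knockdown level
#'
#' The observed (noise-free) phenotype of a cell is the gene's true
#' phenotype scaled by the knockdown-response function evaluated at the
#' realised knockdown: `l * f(x)`. Genes with `l = 0` (wild-type and
#' negative controls) return 0 at any knockdown.
#'
#' @param x Knockdown fraction(s) in \[0, 1\].
#' @param true_phenotype Gene phenotype(s) `l` in \[-1, 1\].
#' @inheritParams response_fraction
#' @return Signed phenotype(s); same sign as `true_phenotype` or zero.
#' @examples
#' cell_phenotype(0.5, 0.6, "linear")  # 0.3
#' @export
cell_phenotype <- function(x, true_phenotype, kind, p = NA_real_, k = NA_real_) {
  true_phenotype * response_fraction(x, kind, p, k)
}

#' Write a genome to a tab-delimited file
#'
#' @param genome A genome data frame from [build_genome()].
#' @param path Output file path.
#' @export
write_genome <- function(genome, path) {
  write_tsv_impl(genome, path)
}
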