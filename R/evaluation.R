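#' Overlap between called and actual top hit genes
#'
#' The actual top-`n` genes are those with the largest absolute true
#' phenotype (ties broken by ascending `gene_id`); the called top-`n` are
#' the first `n` rows of the ranking. Returns the size of the intersection
#' divided by `n`.
#'
#' @param ranked_genes Ranked gene results from [rank_genes()].
#' @param genome Genome data frame with the ground truth.
#' @param n Number of top genes to compare (default 50).
#' @return The overlap fraction in \[0, 1\].
#' @export
top_overlap <- function(ranked_genes, genome, n = 50) {
  if (n > nrow(genome)) stop("n exceeds the number of genes")
  ord <- order(-abs(genome$true_phenotype), genome$gene_id)
  actual <- genome$gene_id[ord][seq_len(n)]
  called_ord <- order(ranked_genes$rank)
  called <- ranked_genes$gene_id[called_ord][seq_len(n)]
  length(intersect(actual, called)) / n
}

#' Area under the precision-recall curve (lower trapezoidal estimator)
#'
#' Genes are sorted by descending score and a precision-recall point is
#' computed at every achievable threshold (tied scores collapse into a
#' single point). The curve is anchored at recall 0 with the first point's
#' precision and always reaches recall 1; the area is the trapezoidal sum
#' over linear interpolation between successive achievable points, a
#' robust lower-bound style estimator for skewed class ratios.
#'
#' @param scores Numeric ranking scores, higher = more confidently a hit.
#' @param classes Gene class labels aligned with `scores`.
#' @param positive_classes Labels counted as true hits (default: the two
#'   hit classes; wild-type and negative-control genes are negatives).
#' @return The estimated area in \[0, 1\].
#' @examples
#' auprc(c(3, 2, 1), c("positive_hit", "wildtype", "wildtype"))  # 1
#' @export
auprc <- function(scores, classes,
                  positive_classes = c("positive_hit", "negative_hit")) {
  labels <- classes %in% positive_classes
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative label")
  }
  ord <- order(-scores)
  s <- scores[ord]
  lab <- labels[ord]
  # threshold group boundaries: last index of each distinct score
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(lab)[ends]
  pred_pos <- ends
  recall <- tp / n_pos
  precision <- tp / pred_pos
  # anchor at recall 0 with the first achievable precision
  r <- c(0, recall)
  p <- c(precision[1], precision)
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

#' Theoretical guide phenotype
#'
#' The deterministic phenotype expected for a guide: the knockdown level
#' the guide is expected to realise, mapped through the gene's
#' knockdown-response function and scaled by the true phenotype. CRISPRi
#' guides (and low-activity CRISPRn guides) realise their knockdown
#' efficiency directly; active CRISPRn guides average the response over the
#' stochastic 1/9 - 4/9 - 4/9 knockout outcome mix.
#'
#' @param library Library data frame.
#' @param genome Genome data frame.
#' @param mode `"CRISPRi"` or `"CRISPRn"`; defaults to the library's mode.
#' @return Numeric vector of theoretical phenotypes, one per guide.
#' @export
guide_theoretical_phenotype <- function(library, genome,
                                        mode = attr(library, "mode")) {
  if (is.null(mode)) mode <- "CRISPRi"
  gi <- match(library$gene_id, genome$gene_id)
  l <- genome$true_phenotype[gi]
  kind <- genome$response_kind[gi]
  p <- genome$p[gi]
  k <- genome$k[gi]
  theo <- cell_phenotype(library$efficiency, l, kind, p, k)
  if (mode == "CRISPRn") {
    active <- library$high_activity & library$efficiency >= 1
    if (any(active)) {
      out <- crisprn_outcomes()
      mix <- rep(0, sum(active))
      for (i in seq_along(out$knockdown)) {
        mix <- mix + out$prob[i] *
          cell_phenotype(out$knockdown[i], l[active], kind[active],
                         p[active], k[active])
      }
      theo[active] <- mix
    }
  }
  theo
}

#' Signal, noise and signal-to-noise ratio of a screen
#'
#' The signal of a true-hit gene is the mean, over its non-dropped guides,
#' of the observed log2 fold change divided by the guide's theoretical
#' phenotype (guides with theoretical phenotype 0 are excluded); the screen
#' signal is the median of this quantity over true-hit genes. The noise is
#' the standard deviation of the negative-control guide phenotypes, and
#' SNR is their ratio (reported as `NA` when the noise is zero).
#'
#' @param guide_results Output of [guide_phenotypes()].
#' @param genome Genome data frame.
#' @param library Library data frame.
#' @param mode Screen mode; defaults to the library's mode.
#' @return A list with elements `signal`, `noise` and `snr`.
#' @export
signal_noise <- function(guide_results, genome, library,
                         mode = attr(library, "mode")) {
  theo <- guide_theoretical_phenotype(library, genome, mode)
  theo <- theo[match(guide_results$guide_id, library$guide_id)]
  ok <- !guide_results$dropped
  hit <- guide_results$class %in% c("positive_hit", "negative_hit")
  use <- ok & hit & theo != 0
  if (!any(use)) stop("no usable guides on true-hit genes")
  ratio <- guide_results$log2fc[use] / theo[use]
  gene_signal <- vapply(split(ratio, guide_results$gene_id[use]),
                        mean, numeric(1))
  signal <- stats::median(gene_signal)
  ctrl <- guide_results$log2fc[ok & guide_results$class == "negative_control"]
  if (length(ctrl) < 2) stop("need at least 2 negative-control guides")
  noise <- stats::sd(ctrl)
  snr <- if (noise > 0) signal / noise else NA_real_
  list(signal = signal, noise = noise, snr = snr)
}

#' Full screen-performance metrics
#'
#' Convenience wrapper computing the top-hit overlap, AUPRC and
#' signal/noise metrics for one simulated screen.
#'
#' @param ranked_genes Output of [rank_genes()].
#' @param guide_results Output of [guide_phenotypes()].
#' @param genome,library Ground truth and library data frames.
#' @param top_n Size of the top-hit lists compared (default 50).
#' @param positive_classes Hit classes used for the AUPRC labels.
#' @return A one-row data frame with columns `overlap`, `auprc`, `signal`,
#'   `noise`, `snr`.
#' @export
screen_metrics <- function(ranked_genes, guide_results, genome, library,
                           top_n = 50,
                           positive_classes = c("positive_hit",
                                                "negative_hit")) {
  sn <- signal_noise(guide_results, genome, library)
  data.frame(
    overlap = top_overlap(ranked_genes, genome, top_n),
    auprc = auprc(ranked_genes$score, ranked_genes$class, positive_classes),
    signal = sn$signal,
    noise = sn$noise,
    snr = sn$snr
  )
}
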