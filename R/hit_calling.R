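#' Per-guide phenotypes from a two-bin count table
#'
#' The observed phenotype of an sgRNA is the log2 ratio of its frequencies
#' in the two comparison bins, with bin 2 (high reporter / tn) in the
#' numerator:
#' `log2fc = log2(freq_bin2 / freq_bin1)` where
#' `freq_b = (reads_b + pseudocount) / (depth_b + pseudocount * n_guides)`.
#' The pseudocount keeps strongly depleted guides informative; guides with
#' zero reads in both bins carry no information and are flagged `dropped`
#' (their `log2fc` is `NA`).
#'
#' @param counts Count table from [build_count_table()] or
#'   [read_count_table()].
#' @param pseudocount Non-negative number added to every guide's reads in
#'   both bins.
#' @return The count table with columns `log2fc` and `dropped` appended.
#' @examples
#' tab <- data.frame(guide_id = 1:2, gene_id = 1:2,
#'                   counts_bin1 = c(100, 2), counts_bin2 = c(100, 8))
#' guide_phenotypes(tab, pseudocount = 0)$log2fc  # 0 and 2
#' @export
guide_phenotypes <- function(counts, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  d1 <- sum(counts$counts_bin1)
  d2 <- sum(counts$counts_bin2)
  if (d1 <= 0 || d2 <= 0) stop("both bins must have positive total reads")
  n_guides <- nrow(counts)
  f1 <- (counts$counts_bin1 + pseudocount) / (d1 + pseudocount * n_guides)
  f2 <- (counts$counts_bin2 + pseudocount) / (d2 + pseudocount * n_guides)
  counts$log2fc <- log2(f2 / f1)
  counts$dropped <- counts$counts_bin1 == 0 & counts$counts_bin2 == 0
  counts$log2fc[counts$dropped] <- NA_real_
  counts
}

# Two-sided Mann-Whitney rank-sum p-value. Delegates to wilcox.test, which
# uses the exact null distribution for small tie-free samples and the
# normal approximation with tie and continuity corrections otherwise.
mw_pvalue <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' Gene-level statistics from guide phenotypes
#'
#' The gene phenotype is the arithmetic mean of its member guides' log2
#' fold changes (dropped guides excluded). Significance is a two-sided
#' Mann-Whitney rank-sum test of the member guide phenotypes against the
#' phenotypes of all negative-control sgRNAs. The ranking score is
#' `|phenotype| * -log10(p)`, with `-log10(p)` capped at 300. Genes whose
#' guides all dropped out get phenotype 0, p = 1 and score 0.
#'
#' @param guide_results Output of [guide_phenotypes()]; must contain a
#'   `class` column identifying `negative_control` genes (used to form the
#'   null phenotype set).
#' @return A data frame with one row per gene: `gene_id`, `class`,
#'   `n_guides`, `phenotype`, `p_value`, `score`.
#' @examples
#' tab <- data.frame(guide_id = 1:6, gene_id = rep(1:2, each = 3),
#'                   class = rep(c("positive_hit", "negative_control"), each = 3),
#'                   counts_bin1 = c(10, 10, 10, 80, 80, 80),
#'                   counts_bin2 = c(80, 80, 80, 80, 80, 80))
#' gene_stats(guide_phenotypes(tab))
#' @export
gene_stats <- function(guide_results) {
  if (!"class" %in% names(guide_results)) {
    stop("guide_results must carry a 'class' column")
  }
  ok <- !guide_results$dropped
  controls <- guide_results$log2fc[ok &
                                     guide_results$class == "negative_control"]
  if (length(controls) < 2) {
    stop("need at least 2 non-dropped negative-control guide phenotypes")
  }
  genes <- unique(guide_results[, c("gene_id", "class")])
  phen <- numeric(nrow(genes))
  pval <- numeric(nrow(genes))
  by_gene <- split(guide_results$log2fc[ok], guide_results$gene_id[ok])
  for (i in seq_len(nrow(genes))) {
    fc <- by_gene[[as.character(genes$gene_id[i])]]
    if (is.null(fc) || length(fc) == 0) {
      phen[i] <- 0
      pval[i] <- 1
    } else {
      phen[i] <- mean(fc)
      pval[i] <- mw_pvalue(fc, controls)
    }
  }
  n_ok <- vapply(split(ok, guide_results$gene_id), sum, numeric(1))
  data.frame(
    gene_id = genes$gene_id,
    class = genes$class,
    n_guides = as.integer(n_ok[as.character(genes$gene_id)]),
    phenotype = phen,
    p_value = pval,
    score = abs(phen) * pmin(-log10(pval), 300),
    stringsAsFactors = FALSE
  )
}

#' Rank genes by their hit-calling score
#'
#' Orders genes by descending score; ties are broken by ascending
#' `gene_id`. Appends a `rank` column.
#'
#' @param gene_results Output of [gene_stats()].
#' @return The input sorted into rank order with a `rank` column.
#' @export
rank_genes <- function(gene_results) {
  ord <- order(-gene_results$score, gene_results$gene_id)
  out <- gene_results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write gene results to a tab-delimited file
#'
#' @param gene_results Output of [rank_genes()] or [gene_stats()].
#' @param path File path.
#' @export
write_gene_results <- function(gene_results, path) {
  write_tsv_impl(gene_results, path)
}
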