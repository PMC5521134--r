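make_counts <- function(c1, c2, gene_id = seq_along(c1),
                        class = rep("wildtype", length(c1))) {
  data.frame(guide_id = seq_along(c1), gene_id = gene_id, class = class,
             counts_bin1 = c1, counts_bin2 = c2, stringsAsFactors = FALSE)
}

test_that("log2 fold changes follow the pseudocounted frequency ratio", {
  # equal reads at equal depth -> 0; 2 vs 8 -> log2(4) = 2
  tab <- make_counts(c(100, 2, 8), c(100, 8, 2))
  res <- guide_phenotypes(tab, pseudocount = 0)
  expect_equal(res$log2fc, c(0, 2, -2))

  # depletion to zero reads stays finite through the pseudocount:
  # equal depths, so log2fc = log2((50 + 0.5) / (0 + 0.5)) = log2(101)
  tab2 <- make_counts(c(0, 50, rep(40, 98)), c(50, 0, rep(40, 98)))
  res2 <- guide_phenotypes(tab2, pseudocount = 0.5)
  expect_equal(res2$log2fc[1], log2(101), tolerance = 1e-12)
  expect_equal(res2$log2fc[1], 6.658, tolerance = 1e-3)

  # zero reads in both bins -> dropped, no phenotype
  tab3 <- make_counts(c(0, 10), c(0, 10))
  res3 <- guide_phenotypes(tab3)
  expect_true(res3$dropped[1])
  expect_true(is.na(res3$log2fc[1]))
  expect_false(res3$dropped[2])
})

test_that("swapping the bins negates log2fc and preserves p-values", {
  set.seed(1)
  c1 <- rpois(60, 50)
  c2 <- rpois(60, 50)
  cls <- rep(c("positive_hit", "wildtype", "negative_control"), each = 20)
  tab <- make_counts(c1, c2, gene_id = rep(1:12, each = 5),
                     class = rep(cls[seq(1, 60, by = 5)], each = 5))
  fwd <- guide_phenotypes(tab)
  swapped <- tab
  swapped$counts_bin1 <- tab$counts_bin2
  swapped$counts_bin2 <- tab$counts_bin1
  rev <- guide_phenotypes(swapped)
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(gene_stats(rev)$p_value, gene_stats(fwd)$p_value)
  expect_equal(gene_stats(rev)$phenotype, -gene_stats(fwd)$phenotype)
})

test_that("Mann-Whitney p-values match exact enumeration for small samples", {
  set.seed(2)
  for (n1 in 1:5) {
    for (n2 in seq_len(10 - n1)) {
      x <- rnorm(n1)
      y <- rnorm(n2)
      expect_equal(screensim:::mw_pvalue(x, y), mw_exact_p(x, y),
                   tolerance = 1e-10,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("gene statistics reproduce the enumerated rank-sum example", {
  # member phenotypes {1,2,3} vs controls {4,5,6}: exact two-sided p = 2/20
  gr <- data.frame(
    guide_id = 1:9,
    gene_id = rep(1:3, each = 3),
    class = rep(c("positive_hit", "negative_control", "wildtype"), each = 3),
    log2fc = c(1, 2, 3, 4, 5, 6, 4.5, 5.5, 3.5),
    dropped = FALSE
  )
  gs <- gene_stats(gr)
  expect_equal(gs$p_value[gs$gene_id == 1], 0.1)
  expect_equal(gs$phenotype[gs$gene_id == 1], 2)
  # score = |phenotype| * -log10(p)
  expect_equal(gs$score, abs(gs$phenotype) * pmin(-log10(gs$p_value), 300))
})

test_that("genes with all guides dropped are scored as null", {
  gr <- data.frame(
    guide_id = 1:7,
    gene_id = c(1, 1, 2, 2, 2, 3, 3),
    class = c("positive_hit", "positive_hit", "negative_control",
              "negative_control", "negative_control", "wildtype", "wildtype"),
    log2fc = c(NA, NA, 0.5, -0.2, 0.1, 0.3, 0.4),
    dropped = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  gs <- gene_stats(gr)
  row <- gs[gs$gene_id == 1, ]
  expect_equal(row$phenotype, 0)
  expect_equal(row$p_value, 1)
  expect_equal(row$score, 0)
  expect_equal(row$n_guides, 0L)
})

test_that("ranking is by descending score with gene-id tie-break", {
  gs <- data.frame(gene_id = c(3, 1, 2), class = "wildtype",
                   n_guides = 5L, phenotype = c(1, 1, 2),
                   p_value = c(0.1, 0.1, 0.1),
                   score = c(1, 1, 4))
  ranked <- rank_genes(gs)
  expect_equal(ranked$gene_id, c(2, 1, 3))
  expect_equal(ranked$rank, 1:3)
})
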