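test_that("top overlap handles identity, disjoint and partial cases", {
  genome <- data.frame(gene_id = 1:100,
                       class = rep(c("positive_hit", "wildtype"), c(50, 50)),
                       true_phenotype = c(seq(1, 0.5, length.out = 50),
                                          rep(0, 50)))
  perfect <- ranked_from_scores(1:100, 100:1)
  expect_equal(top_overlap(perfect, genome, 50), 1.0)

  inverted <- ranked_from_scores(1:100, 1:100)
  expect_equal(top_overlap(inverted, genome, 50), 0.0)

  # 10 of the 50 called hits replaced by non-hits -> 40/50
  scores <- rep(0, 100)
  scores[c(1:40, 91:100)] <- 100:51
  partial <- ranked_from_scores(1:100, scores)
  expect_equal(top_overlap(partial, genome, 50), 0.8)
  expect_error(top_overlap(perfect, genome, 101), "exceeds")
})

test_that("top overlap depends only on the two top-n sets", {
  genome <- data.frame(gene_id = 1:60,
                       class = rep(c("positive_hit", "wildtype"), c(20, 40)),
                       true_phenotype = c(runif(20, 0.1, 1), rep(0, 40)))
  ranked <- ranked_from_scores(1:60, rnorm(60))
  shuffled <- ranked[sample(nrow(ranked)), ]
  expect_equal(top_overlap(shuffled, genome, 20),
               top_overlap(ranked, genome, 20))
})

test_that("auprc is 1 for perfect ranking and prevalence for a constant score", {
  cls <- rep(c("positive_hit", "wildtype"), c(3, 7))
  expect_equal(auprc(10:1, cls), 1.0)
  expect_equal(auprc(rep(2, 10), cls), 0.3)
  expect_error(auprc(1:3, rep("wildtype", 3)), "positive")
})

test_that("auprc matches brute-force threshold integration on random instances", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    # draw from few distinct values so that tied scores are exercised
    scores <- sample(seq_len(8), n, replace = TRUE) / 2
    labels <- logical(n)
    labels[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    cls <- ifelse(labels, "positive_hit", "wildtype")
    expect_equal(auprc(scores, cls), auprc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("theoretical CRISPRn phenotypes average the knockout outcome mix", {
  genome <- data.frame(gene_id = 1:2, class = c("positive_hit", "wildtype"),
                       true_phenotype = c(0.8, 0),
                       response_kind = "linear", p = NA_real_, k = NA_real_)
  lib <- data.frame(guide_id = 1:4, gene_id = c(1, 1, 2, 2),
                    high_activity = c(TRUE, FALSE, TRUE, FALSE),
                    efficiency = c(1, 0.1, 1, 0.05),
                    plasmid_frequency = 0.25)
  theo <- guide_theoretical_phenotype(lib, genome, mode = "CRISPRn")
  # active guide on a linear gene: l * (1/9*0 + 4/9*0.5 + 4/9*1) = l * 2/3
  expect_equal(theo[1], 0.8 * 2 / 3)
  expect_equal(theo[2], 0.8 * 0.1)
  expect_equal(theo[3:4], c(0, 0))
})

test_that("signal is 1 when observed phenotypes equal theory, snr missing at zero noise", {
  genome <- data.frame(gene_id = 1:3,
                       class = c("positive_hit", "negative_hit",
                                 "negative_control"),
                       true_phenotype = c(0.5, -0.4, 0),
                       response_kind = "linear", p = NA_real_, k = NA_real_)
  lib <- data.frame(guide_id = 1:6, gene_id = rep(1:3, each = 2),
                    high_activity = TRUE,
                    efficiency = c(0.9, 0.8, 0.9, 0.7, 0.9, 0.9),
                    plasmid_frequency = 1 / 6)
  attr(lib, "mode") <- "CRISPRi"
  theo <- guide_theoretical_phenotype(lib, genome)
  gr <- data.frame(guide_id = 1:6, gene_id = rep(1:3, each = 2),
                   class = rep(genome$class, each = 2),
                   log2fc = theo, dropped = FALSE)
  gr$log2fc[5:6] <- c(0.1, 0.1)  # controls: equal -> zero noise
  sn <- signal_noise(gr, genome, lib)
  expect_equal(sn$signal, 1.0)
  expect_equal(sn$noise, 0)
  expect_true(is.na(sn$snr))
})

test_that("doubling sequencing depth reduces the noise metric", {
  set.seed(6)
  g <- build_genome(genome_config(n_genes = 60))
  lib <- build_library(g, library_config())
  pool <- infect(lib, g, infection_params(representation = 50))
  bins <- facs_sort(pool, facs_params(representation = 50))
  noise_at <- function(rep_reads) {
    tab <- build_count_table(bins$low, bins$high, lib, g,
                             seq_params(representation = rep_reads))
    gr <- guide_phenotypes(tab)
    sd(gr$log2fc[!gr$dropped & gr$class == "negative_control"])
  }
  shallow <- mean(replicate(25, noise_at(20)))
  deep <- mean(replicate(25, noise_at(200)))
  expect_lt(deep, shallow)
})

test_that("estimated phenotypes recover the truth at high representation", {
  cfg <- screen_config(
    genome = genome_config(n_genes = 200),
    infection = infection_params(representation = 1000),
    facs = facs_params(representation = 1000),
    sequencing = seq_params(representation = 1000)
  )
  rhos <- vapply(1:5, function(i) {
    res <- run_screen(cfg, seed = 100 + i)
    hits <- res$genome$gene_id[res$genome$class %in%
                                 c("positive_hit", "negative_hit")]
    est <- res$gene_results$phenotype[match(hits, res$gene_results$gene_id)]
    truth <- res$genome$true_phenotype[match(hits, res$genome$gene_id)]
    cor(est, truth, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.8)
})
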