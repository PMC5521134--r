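test_that("identical config and seed give bit-identical screens", {
  cfg <- tiny_config()
  r1 <- run_screen(cfg, seed = 7)
  r2 <- run_screen(cfg, seed = 7)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$gene_results, r2$gene_results)
})

test_that("a FACS CRISPRi screen beats the random baseline", {
  res <- run_screen(tiny_config(n_genes = 200, representation = 100),
                    seed = 11)
  prevalence <- mean(res$genome$class %in% c("positive_hit", "negative_hit"))
  expect_gt(res$metrics$overlap, 0)
  expect_gt(res$metrics$auprc, prevalence)
})

test_that("growth screens deplete negative-hit genes", {
  cfg <- screen_config(
    selection = "growth",
    genome = genome_config(n_genes = 150,
                           class_fractions = c(wildtype = 0.85,
                                               negative_control = 0.05,
                                               negative_hit = 0.10)),
    infection = infection_params(representation = 100),
    growth = growth_params(num_passages = 3, representation = 100),
    sequencing = seq_params(representation = 100)
  )
  res <- run_screen(cfg, seed = 13)
  neg <- res$gene_results$phenotype[res$gene_results$class == "negative_hit"]
  expect_lt(mean(neg), 0)
})

test_that("hit genes rank ahead of wild-type genes in a clean screen", {
  res <- run_screen(tiny_config(n_genes = 200, representation = 100),
                    seed = 17)
  strong <- res$genome$gene_id[abs(res$genome$true_phenotype) >= 0.5]
  wt <- res$genome$gene_id[res$genome$class == "wildtype"]
  rk <- res$gene_results$rank
  names(rk) <- res$gene_results$gene_id
  expect_lt(median(rk[as.character(strong)]), median(rk[as.character(wt)]))
})

test_that("replicate seeds are a pure function of base seed and indices", {
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  expect_false(derive_seed(1, 2, 3) == derive_seed(1, 3, 2))
  expect_false(derive_seed(1, 1, 1) == derive_seed(2, 1, 1))
  expect_true(derive_seed(.Machine$integer.max, 99, 99) > 0)
})

test_that("sweeps produce one row per run plus a summary, reproducibly", {
  cfg <- tiny_config(n_genes = 60, representation = 30)
  sw <- run_sweep(cfg, list(facs.bin_fraction = c(0.25)), replicates = 3,
                  base_seed = 5)
  expect_equal(nrow(sw$runs), 3)
  expect_equal(nrow(sw$summary), 1)
  expect_true(all(is.na(sw$runs$error)))
  expect_true(all(c("auprc_mean", "auprc_lo", "auprc_hi") %in%
                    names(sw$summary)))

  sw2 <- run_sweep(cfg, list(facs.bin_fraction = c(0.25)), replicates = 3,
                   base_seed = 5)
  expect_identical(sw$runs, sw2$runs)
})

test_that("the joint representation path sets all three stages", {
  cfg <- tiny_config()
  cfg2 <- screensim:::set_config_param(cfg, "representation", 200)
  expect_equal(cfg2$infection$representation, 200)
  expect_equal(cfg2$facs$representation, 200)
  expect_equal(cfg2$growth$representation, 200)
  expect_equal(cfg2$sequencing$representation, 200)
  expect_error(screensim:::set_config_param(cfg, "facs.nope", 1), "unknown")
  # "selection.<param>" aliases the active selection stage
  cfg3 <- screensim:::set_config_param(tiny_config("growth"),
                                       "selection.num_passages", 7)
  expect_equal(cfg3$growth$num_passages, 7)
  cfg4 <- screensim:::set_config_param(cfg, "selection.bin_fraction", 0.1)
  expect_equal(cfg4$facs$bin_fraction, 0.1)
})

test_that("snr_curve tabulates one row per bin fraction", {
  cfg <- tiny_config(n_genes = 60, representation = 30)
  curve <- snr_curve(cfg, bin_fractions = 0.25, replicates = 2)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$bin_fraction, 0.25)
  expect_true(all(c("signal_mean", "noise_mean", "snr_mean") %in%
                    names(curve)))
})

test_that("count tables and configs round-trip through their file formats", {
  res <- run_screen(tiny_config(n_genes = 30, representation = 20,
                                top_n = 10), seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write_count_table(res$counts, tmp)
  back <- read_count_table(tmp)
  expect_equal(back$counts_bin1, res$counts$counts_bin1)
  expect_equal(back$counts_bin2, res$counts$counts_bin2)
  expect_equal(back$gene_id, res$counts$gene_id)

  cfgfile <- tempfile(fileext = ".yaml")
  cfg <- tiny_config(selection = "growth", mode = "CRISPRn")
  write_screen_config(cfg, cfgfile)
  cfg2 <- read_screen_config(cfgfile)
  expect_equal(cfg2$mode, "CRISPRn")
  expect_equal(cfg2$selection, "growth")
  expect_equal(cfg2$growth$num_passages, cfg$growth$num_passages)
  expect_equal(cfg2$genome$class_fractions, cfg$genome$class_fractions)
  expect_equal(cfg2$library$mode, "CRISPRn")
  unlink(c(tmp, cfgfile))
})

test_that("external count tables can be analyzed standalone", {
  res <- run_screen(tiny_config(n_genes = 50, representation = 30), seed = 9)
  tmp <- tempfile(fileext = ".tsv")
  write_count_table(res$counts, tmp)
  out <- analyze_count_table(read_count_table(tmp))
  expect_equal(out$gene_results$score, res$gene_results$score)
  unlink(tmp)
})
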