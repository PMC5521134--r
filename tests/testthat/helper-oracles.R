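# Independent oracles used across the suite. These deliberately use
# different algorithms (enumeration, brute force, closed forms) from the
# package code paths they check.

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled observations into the two groups (tie-free data only).
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Brute-force AUPRC: recompute the confusion matrix from scratch at every
# achievable threshold, then integrate the anchored PR polyline with
# pracma's trapezoid rule.
auprc_bruteforce <- function(scores, labels) {
  n_pos <- sum(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pr <- t(vapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    c(recall = tp / n_pos, precision = tp / sum(pred))
  }, numeric(2)))
  r <- unname(c(0, pr[, "recall"]))
  p <- unname(c(pr[1, "precision"], pr[, "precision"]))
  unname(pracma::trapz(r, p))
}

# Mean of a Gaussian censored (clamped) to [lo, hi].
censored_normal_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  lo * stats::pnorm(a) + hi * stats::pnorm(b, lower.tail = FALSE) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sigma * (stats::dnorm(b) - stats::dnorm(a))
}

# A small, fast screen configuration for end-to-end tests.
tiny_config <- function(selection = "facs", mode = "CRISPRi",
                        n_genes = 100, representation = 50, ...) {
  screen_config(
    mode = mode,
    selection = selection,
    genome = genome_config(n_genes = n_genes),
    library = library_config(),
    infection = infection_params(representation = representation),
    facs = facs_params(representation = representation),
    growth = growth_params(num_passages = 3,
                           representation = representation),
    sequencing = seq_params(representation = representation),
    ...
  )
}

# Gene ranking built directly from scores (bypasses hit calling).
ranked_from_scores <- function(gene_id, score, class = "wildtype") {
  rank_genes(data.frame(gene_id = gene_id, class = class, n_guides = 5L,
                        phenotype = score, p_value = 0.5, score = score))
}

# Manually constructed cell pool (bypasses infection).
make_pool <- function(guide_id, phenotype, cells,
                      n_guides = max(guide_id), knockdown = 1) {
  screensim:::new_cell_pool(guide_id, rep_len(knockdown, length(guide_id)),
                            phenotype, cells, n_guides)
}
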