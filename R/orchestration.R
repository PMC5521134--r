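#' Full screen configuration
#'
#' Bundles the per-stage parameter objects into one configuration for
#' [run_screen()]. The library mode is forced to the screen mode, and the
#' selection-specific parameter block must match the selection type.
#'
#' @param mode Screen mode, `"CRISPRi"` or `"CRISPRn"`.
#' @param selection Selection strategy, `"facs"` or `"growth"`.
#' @param genome A [genome_config()].
#' @param library A [library_config()] (its `mode` is overridden).
#' @param infection An [infection_params()].
#' @param facs A [facs_params()] (used when `selection = "facs"`).
#' @param growth A [growth_params()] (used when `selection = "growth"`).
#' @param sequencing A [seq_params()].
#' @param pseudocount Pseudocount for [guide_phenotypes()].
#' @param top_n Top-list size for [top_overlap()].
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(mode = c("CRISPRi", "CRISPRn"),
                          selection = c("facs", "growth"),
                          genome = genome_config(),
                          library = library_config(),
                          infection = infection_params(),
                          facs = facs_params(),
                          growth = growth_params(),
                          sequencing = seq_params(),
                          pseudocount = 0.5,
                          top_n = 50) {
  mode <- match.arg(mode)
  selection <- match.arg(selection)
  library$mode <- mode
  stopifnot(inherits(genome, "genome_config"),
            inherits(library, "library_config"),
            inherits(infection, "infection_params"),
            inherits(facs, "facs_params"),
            inherits(growth, "growth_params"),
            inherits(sequencing, "seq_params"),
            pseudocount >= 0, top_n >= 1)
  structure(list(mode = mode, selection = selection, genome = genome,
                 library = library, infection = infection, facs = facs,
                 growth = growth, sequencing = sequencing,
                 pseudocount = pseudocount, top_n = as.integer(top_n)),
            class = "screen_config")
}

#' Run one end-to-end simulated screen
#'
#' Executes the whole pipeline: genome, library, infection, selection
#' (FACS sort or growth/passaging), sequencing of both comparison bins,
#' guide and gene-level hit calling, and performance metrics against the
#' ground truth. Fully reproducible: the same `(config, seed)` pair yields
#' bit-identical results.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed for the run; if `NULL` the current random
#'   stream is used.
#' @return A list of class `screen_result` with elements `genome`,
#'   `library`, `counts`, `guide_results`, `gene_results` (ranked),
#'   `metrics` (one-row data frame) and `seed`.
#' @examples
#' \donttest{
#' cfg <- screen_config(genome = genome_config(n_genes = 50),
#'                      infection = infection_params(representation = 20),
#'                      facs = facs_params(representation = 20),
#'                      sequencing = seq_params(representation = 20))
#' res <- run_screen(cfg, seed = 1)
#' res$metrics
#' }
#' @export
run_screen <- function(config, seed = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (!is.null(seed)) set.seed(seed)
  genome <- build_genome(config$genome)
  library <- build_library(genome, config$library)
  pool <- infect(library, genome, config$infection, mode = config$mode)
  if (config$selection == "facs") {
    bins <- facs_sort(pool, config$facs)
    labels <- c("low", "high")
  } else {
    bins <- grow_pool(pool, config$growth)
    labels <- c("t0", "tn")
  }
  counts <- build_count_table(bins[[1]], bins[[2]], library, genome,
                              config$sequencing, bin_labels = labels)
  guide_results <- guide_phenotypes(counts, config$pseudocount)
  gene_results <- rank_genes(gene_stats(guide_results))
  metrics <- screen_metrics(gene_results, guide_results, genome, library,
                            top_n = config$top_n)
  structure(list(genome = genome, library = library, counts = counts,
                 guide_results = guide_results, gene_results = gene_results,
                 metrics = metrics, seed = seed),
            class = "screen_result")
}

#' Derive a replicate seed from a base seed and indices
#'
#' Pure function of its arguments: mixes the base seed and any number of
#' integer indices through a Lehmer-style multiplicative congruential hash
#' modulo 2^31 - 1, decorrelating the random streams of sweep cells and
#' replicates without any seed bookkeeping.
#'
#' @param base_seed Integer base seed.
#' @param ... Integer indices (e.g. grid cell index, replicate index).
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(base_seed, ...) {
  m <- 2147483647
  mult <- 69621  # keeps products below 2^53 for exact double arithmetic
  h <- as.numeric(base_seed) %% m
  for (idx in c(..., 0)) {
    h <- (h * mult + as.numeric(idx) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# set one parameter by dotted path, e.g. "facs.bin_fraction" or
# "growth.num_passages"; the special path "representation" sets the
# infection, selection-bottleneck and sequencing representations jointly
set_config_param <- function(config, path, value) {
  if (identical(path, "representation")) {
    config$infection$representation <- value
    config$facs$representation <- value
    config$growth$representation <- value
    config$sequencing$representation <- value
    return(config)
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  # "selection.<param>" addresses whichever selection stage is active
  if (parts[1] == "selection" && length(parts) == 2) {
    parts[1] <- if (config$selection == "facs") "facs" else "growth"
  }
  if (length(parts) == 1) {
    if (!parts %in% names(config)) stop("unknown config parameter: ", path)
    config[[parts]] <- value
  } else if (length(parts) == 2) {
    if (!parts[1] %in% names(config) ||
        !parts[2] %in% names(config[[parts[1]]])) {
      stop("unknown config parameter: ", path)
    }
    config[[parts[1]]][[parts[2]]] <- value
  } else {
    stop("parameter paths have at most two components: ", path)
  }
  config
}

#' Run a seeded replicate sweep over a parameter grid
#'
#' Builds the full factorial grid of the supplied parameter values, runs
#' `replicates` seeded screens per grid cell, and collects all metrics in
#' a tidy table. Replicate seeds are a pure function of
#' `(base_seed, cell index, replicate index)` via [derive_seed()], so any
#' single cell can be re-run in isolation. A failed run is recorded in the
#' `error` column and the sweep continues.
#'
#' @param config Base [screen_config()].
#' @param sweep Named list: names are dotted parameter paths (e.g.
#'   `"facs.bin_fraction"`, `"growth.num_passages"`; `"selection.<param>"`
#'   addresses whichever selection stage is active, and the special path
#'   `"representation"` sets all three stage representations jointly);
#'   values are the grids.
#' @param replicates Replicates per grid cell.
#' @param base_seed Base seed for [derive_seed()].
#' @param conf Confidence level for the summary intervals (default 0.95).
#' @return A list of class `sweep_result` with `runs` (one row per run:
#'   swept parameters, `replicate`, `seed`, the five metrics, `error`) and
#'   `summary` (per grid cell: mean, SE and normal-approximation confidence
#'   bounds for each metric).
#' @export
run_sweep <- function(config, sweep, replicates = 10, base_seed = 1,
                      conf = 0.95) {
  stopifnot(length(sweep) > 0, all(lengths(sweep) > 0), replicates >= 1)
  grid <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  metric_cols <- c("overlap", "auprc", "signal", "noise", "snr")
  rows <- vector("list", nrow(grid) * replicates)
  n <- 0
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    for (p in names(sweep)) cfg <- set_config_param(cfg, p, grid[[p]][i])
    for (j in seq_len(replicates)) {
      seed <- derive_seed(base_seed, i, j)
      res <- tryCatch(run_screen(cfg, seed), error = function(e) e)
      n <- n + 1
      row <- cbind(grid[i, , drop = FALSE],
                   data.frame(replicate = j, seed = seed))
      if (inherits(res, "error")) {
        row[metric_cols] <- NA_real_
        row$error <- conditionMessage(res)
      } else {
        row[metric_cols] <- res$metrics[metric_cols]
        row$error <- NA_character_
      }
      rows[[n]] <- row
    }
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL

  z <- stats::qnorm(1 - (1 - conf) / 2)
  summ <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- rep(TRUE, nrow(runs))
    for (p in names(sweep)) sel <- sel & runs[[p]] == grid[[p]][i]
    out <- grid[i, , drop = FALSE]
    for (mc in metric_cols) {
      v <- runs[[mc]][sel]
      v <- v[is.finite(v)]
      mu <- mean(v)
      se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
      out[[paste0(mc, "_mean")]] <- mu
      out[[paste0(mc, "_lo")]] <- mu - z * se
      out[[paste0(mc, "_hi")]] <- mu + z * se
    }
    out$n_ok <- sum(is.na(runs$error[sel]))
    out
  })
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary, conf = conf),
            class = "sweep_result")
}

#' Signal-to-noise curve over FACS bin sizes
#'
#' Sweeps the FACS bin fraction over a grid, running seeded replicate
#' screens at each value, and tabulates the mean and confidence interval
#' of the signal, noise and SNR metrics per bin size. Optionally rescales
#' each metric's means by their maximum across the grid (display
#' normalisation; the SNR argmax is unaffected).
#'
#' @param config Base [screen_config()] with `selection = "facs"`.
#' @param bin_fractions Grid of bin fractions in (0, 0.5].
#' @param replicates Seeded replicates per bin fraction.
#' @param base_seed Base seed.
#' @param normalize Rescale each metric's mean column to max 1.
#' @return A data frame with one row per bin fraction (`bin_fraction`,
#'   then `<metric>_mean`, `<metric>_lo`, `<metric>_hi` for signal, noise
#'   and snr), with the per-run table in attribute `"runs"`.
#' @export
snr_curve <- function(config, bin_fractions = seq(0.05, 0.45, by = 0.05),
                      replicates = 10, base_seed = 1, normalize = FALSE) {
  if (length(bin_fractions) < 1) stop("need at least one bin fraction")
  sw <- run_sweep(config, list(facs.bin_fraction = bin_fractions),
                  replicates = replicates, base_seed = base_seed)
  keep <- c("facs.bin_fraction",
            grep("^(signal|noise|snr)_", names(sw$summary), value = TRUE))
  out <- sw$summary[, keep]
  names(out)[1] <- "bin_fraction"
  if (normalize) {
    for (mc in c("signal", "noise", "snr")) {
      mx <- max(out[[paste0(mc, "_mean")]], na.rm = TRUE)
      for (suf in c("_mean", "_lo", "_hi")) {
        out[[paste0(mc, suf)]] <- out[[paste0(mc, suf)]] / mx
      }
    }
  }
  attr(out, "runs") <- sw$runs
  out
}
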