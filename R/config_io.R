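#' Read a screen configuration from a YAML file
#'
#' The YAML document mirrors the [screen_config()] structure: top-level
#' `mode` and nested blocks `genome`, `library`, `infection`, `selection`
#' (with a `type` key of `facs` or `growth` plus that stage's parameters),
#' `sequencing`, `analysis` (`pseudocount`), `evaluation` (`top_n`) and an
#' optional `run` block (`seed`, `replicates`) returned in the
#' `"run"` attribute. Keys use the constructor argument names; omitted
#' keys take the package defaults.
#'
#' @param path Path to the YAML file.
#' @return A [screen_config()] with attribute `"run"`.
#' @export
read_screen_config <- function(path) {
  x <- yaml::read_yaml(path)
  screen_config_from_list(x)
}

call_with <- function(fun, args) {
  if (is.null(args)) args <- list()
  known <- intersect(names(args), names(formals(fun)))
  unknown <- setdiff(names(args), names(formals(fun)))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(fun, args[known])
}

#' Build a screen configuration from a nested list
#'
#' @param x Nested list with the structure described in
#'   [read_screen_config()].
#' @return A [screen_config()] with attribute `"run"`.
#' @export
screen_config_from_list <- function(x) {
  sel <- x$selection %||% list()
  sel_type <- sel$type %||% "facs"
  sel$type <- NULL
  facs <- facs_params()
  growth <- growth_params()
  if (sel_type == "facs") facs <- call_with(facs_params, sel)
  else growth <- call_with(growth_params, sel)
  gen <- x$genome %||% list()
  if (!is.null(gen$class_fractions)) {
    gen$class_fractions <- unlist(gen$class_fractions)
  }
  for (rng in c("positive_range", "negative_range")) {
    if (!is.null(gen[[rng]])) gen[[rng]] <- unlist(gen[[rng]])
  }
  cfg <- screen_config(
    mode = x$mode %||% "CRISPRi",
    selection = sel_type,
    genome = call_with(genome_config, gen),
    library = call_with(library_config, x$library),
    infection = call_with(infection_params, x$infection),
    facs = facs,
    growth = growth,
    sequencing = call_with(seq_params, x$sequencing),
    pseudocount = (x$analysis %||% list())$pseudocount %||% 0.5,
    top_n = (x$evaluation %||% list())$top_n %||% 50
  )
  attr(cfg, "run") <- x$run %||% list()
  cfg
}

#' Echo a screen configuration to YAML
#'
#' Writes the fully resolved configuration (all defaults filled in) so a
#' run can be reproduced from its output directory alone.
#'
#' @param config A [screen_config()].
#' @param path Output YAML path.
#' @export
write_screen_config <- function(config, path) {
  sel_block <- if (config$selection == "facs") {
    c(list(type = "facs"), unclass(config$facs))
  } else {
    c(list(type = "growth"), unclass(config$growth))
  }
  gen <- unclass(config$genome)
  gen$class_fractions <- as.list(gen$class_fractions)
  x <- list(
    mode = config$mode,
    genome = gen,
    library = unclass(config$library),
    infection = unclass(config$infection),
    selection = sel_block,
    sequencing = unclass(config$sequencing),
    analysis = list(pseudocount = config$pseudocount),
    evaluation = list(top_n = config$top_n)
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Hit calling on a count table
#'
#' Runs the analysis half of the pipeline (guide phenotypes, gene
#' statistics, ranking) on a two-bin count table, e.g. one read from disk
#' with [read_count_table()]. The table must carry a `class` column so
#' that negative-control guides can be identified.
#'
#' @param counts Count table data frame.
#' @param pseudocount Pseudocount for [guide_phenotypes()].
#' @return A list with `guide_results` and ranked `gene_results`.
#' @export
analyze_count_table <- function(counts, pseudocount = 0.5) {
  guide_results <- guide_phenotypes(counts, pseudocount)
  gene_results <- rank_genes(gene_stats(guide_results))
  list(guide_results = guide_results, gene_results = gene_results)
}
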