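#' Sequencing parameters
#'
#' Next-generation sequencing of a selected bin is simulated as categorical
#' sampling: guide frequencies in the bin define a categorical
#' distribution, and `representation * n_guides` reads are drawn from it
#' (multinomially, i.e. with replacement, as PCR amplification before
#' sequencing makes reads exchangeable draws). Both bins are sequenced to
#' the same depth.
#'
#' @param representation Reads per library guide.
#' @return A list of class `seq_params`.
#' @export
seq_params <- function(representation = 100) {
  if (representation < 1) stop("representation must be >= 1")
  structure(list(representation = representation), class = "seq_params")
}

#' Sequence one bin of cells
#'
#' Merges knockdown-realisation buckets of the same guide (sequencing sees
#' guides, not repair outcomes), then draws `depth` reads multinomially
#' with the guide cell frequencies as weights. Guides absent from the bin
#' receive zero reads.
#'
#' @param pool A cell pool (one comparison bin).
#' @param depth Total number of reads to draw (>= 1).
#' @return An integer vector of reads indexed by `guide_id`
#'   (length `n_guides`), summing to `depth`.
#' @export
sequence_bin <- function(pool, depth) {
  if (nrow(pool) == 0 || pool_size(pool) == 0) stop("bin must be nonempty")
  if (depth < 1) stop("depth must be >= 1")
  n_guides <- attr(pool, "n_guides")
  per_guide <- vapply(split(pool$cells, factor(pool$guide_id,
                                               levels = seq_len(n_guides))),
                      sum, numeric(1))
  as.integer(stats::rmultinom(1, depth, per_guide))
}

#' Build a two-bin count table from sequenced bins
#'
#' Sequences both comparison bins to the same depth and assembles the
#' interchange count table consumed by the hit-calling step.
#'
#' @param bin1,bin2 Cell pools: the low/high FACS bins or the t0/tn growth
#'   populations (bin2 is the high or tn population).
#' @param library Library data frame from [build_library()].
#' @param genome Genome data frame from [build_genome()].
#' @param params A [seq_params()].
#' @param bin_labels Character vector of length 2 naming the bins.
#' @return A data frame with columns `guide_id`, `gene_id`, `class`,
#'   `counts_bin1`, `counts_bin2`; the labels are stored in attribute
#'   `"bin_labels"`.
#' @export
build_count_table <- function(bin1, bin2, library, genome,
                              params = seq_params(),
                              bin_labels = c("low", "high")) {
  stopifnot(inherits(params, "seq_params"))
  depth <- params$representation * nrow(library)
  counts <- data.frame(
    guide_id = library$guide_id,
    gene_id = library$gene_id,
    class = genome$class[match(library$gene_id, genome$gene_id)],
    counts_bin1 = sequence_bin(bin1, depth),
    counts_bin2 = sequence_bin(bin2, depth),
    stringsAsFactors = FALSE
  )
  attr(counts, "bin_labels") <- bin_labels
  counts
}

#' Read / write the two-bin count table
#'
#' Tab-delimited interchange format with columns `guide_id`, `gene_id`,
#' `class`, `counts_bin1`, `counts_bin2`. Externally produced tables with
#' these columns are accepted by [guide_phenotypes()].
#'
#' @param counts Count table data frame.
#' @param path File path.
#' @export
write_count_table <- function(counts, path) {
  write_tsv_impl(counts, path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("guide_id", "gene_id", "counts_bin1", "counts_bin2")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    stop("count table is missing columns: ", paste(missing, collapse = ", "))
  }
  counts
}
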