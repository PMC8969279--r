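#' Exon count matrix
#'
#' Container for disjoint exon-bin counts across samples with condition labels:
#' the input of the differential exon-usage test.
#'
#' @param counts integer matrix, bins x samples, non-negative; rownames are
#'   bin ids matching `bins$bin_id`.
#' @param bins an `"exon_bins"` data.frame (see [flatten_gene_models()]) with
#'   one row per count row, in the same order.
#' @param condition character/factor of per-sample labels, each `"mock"` or
#'   `"ire1"`.
#' @return an object of class `"exon_count_matrix"` with elements `counts`,
#'   `bins`, `samples`, `condition`.
#' @export
exon_count_matrix <- function(counts, bins, condition) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (nrow(counts) != nrow(bins)) stop("counts rows and bins rows differ")
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) stop("one condition label per sample required")
  if (!all(condition %in% c("mock", "ire1"))) {
    stop("condition labels must be 'mock' or 'ire1'")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- make.unique(paste0(condition, "_s"), sep = "")
  }
  rownames(counts) <- bins$bin_id
  structure(
    list(counts = counts, bins = bins, samples = colnames(counts),
         condition = condition),
    class = "exon_count_matrix"
  )
}

#' @export
print.exon_count_matrix <- function(x, ...) {
  cat(sprintf("<exon_count_matrix> %d bins x %d samples (%d mock, %d ire1), %d gene(s)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "mock"), sum(x$condition == "ire1"),
              length(unique(x$bins$gene_ids))))
  invisible(x)
}

#' Write / read an exon count matrix as TSV
#'
#' Layout: `bin_id`, `gene_id`, then one column per sample. Condition labels
#' are encoded in the sample column names as a `mock_`/`ire1_` prefix and
#' recovered on read.
#'
#' @param m an [exon_count_matrix()].
#' @param path file path.
#' @param bins on read: optional `"exon_bins"` data.frame carrying the full bin
#'   annotation; when omitted a minimal one is reconstructed from the TSV.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(bin_id = m$bins$bin_id, gene_id = m$bins$gene_ids,
                   m$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_atomic(function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, bins = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_cols <- setdiff(names(df), c("bin_id", "gene_id"))
  condition <- sub("_.*$", "", sample_cols)
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  if (is.null(bins)) {
    bins <- data.frame(
      bin_id = df$bin_id, gene_id = df$gene_id, gene_ids = df$gene_id,
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_,
      rank_5to3 = suppressWarnings(as.integer(sub("^.*:E", "", df$bin_id))),
      ambiguous = grepl("+", df$gene_id, fixed = TRUE),
      stringsAsFactors = FALSE
    )
    bins$gene_id[bins$ambiguous] <- NA_character_
    class(bins) <- c("exon_bins", "data.frame")
  } else {
    bins <- bins[match(df$bin_id, bins$bin_id), , drop = FALSE]
  }
  exon_count_matrix(counts, bins, condition)
}
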