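#' Flatten gene models into disjoint exon counting bins
#'
#' Splits the exons of all transcripts into maximal intervals covered by a
#' constant set of (gene, transcript) memberships, in the style of DEXSeq's
#' exon-bin preparation: bins break at every exon boundary of any overlapping
#' transcript, adjacent pieces with identical membership are merged back, and a
#' bin touched by two or more gene ids is flagged `ambiguous` (such exons are
#' kept in the count matrix but excluded from testing and candidate selection).
#'
#' @param x either a list of [transcript_model()] objects or a data.frame of
#'   exon records with columns `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open).
#' @return a data.frame of class `"exon_bins"`, genomically sorted, with columns
#'   `bin_id`, `gene_id` (NA for ambiguous bins), `gene_ids` (all member genes,
#'   `+`-joined), `chrom`, `start`, `end`, `strand`, `rank_5to3` (strand-aware
#'   5' to 3' rank within gene, NA for ambiguous bins) and `ambiguous`.
#' @export
flatten_gene_models <- function(x) {
  rec <- as_exon_records(x)
  if (any(rec$end <= rec$start)) stop("exon with end <= start")
  gr <- GenomicRanges::GRanges(
    rec$chrom, IRanges::IRanges(rec$start + 1L, rec$end), strand = rec$strand)
  dj <- GenomicRanges::disjoin(gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(dj, gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  memb <- vapply(split(sh, qh), function(i) {
    paste(sort(unique(paste(rec$gene_id[i], rec$transcript_id[i], sep = "\t"))),
          collapse = "\n")
  }, character(1))
  genes <- vapply(split(sh, qh), function(i) {
    paste(sort(unique(rec$gene_id[i])), collapse = "+")
  }, character(1))
  strands <- vapply(split(sh, qh), function(i) {
    s <- unique(rec$strand[i]); if (length(s) == 1L) s else "*"
  }, character(1))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dj)),
    start = GenomicRanges::start(dj) - 1L,
    end = GenomicRanges::end(dj),
    gene_ids = genes, strand = strands, memb = memb,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  # merge adjacent pieces with identical (gene, transcript) membership
  keep <- logical(nrow(df))
  out <- df[0, ]
  i <- 1L
  while (i <= nrow(df)) {
    j <- i
    while (j < nrow(df) &&
           df$chrom[j + 1] == df$chrom[i] &&
           df$start[j + 1] == df$end[j] &&
           df$memb[j + 1] == df$memb[i]) {
      j <- j + 1L
    }
    row <- df[i, ]
    row$end <- df$end[j]
    out <- rbind(out, row)
    i <- j + 1L
  }
  out$memb <- NULL
  out$ambiguous <- grepl("+", out$gene_ids, fixed = TRUE)
  out$gene_id <- ifelse(out$ambiguous, NA_character_, out$gene_ids)
  out$rank_5to3 <- NA_integer_
  out$bin_id <- NA_character_
  rownames(out) <- NULL
  # rank and name bins per gene (unambiguous bins only carry a rank)
  for (g in unique(out$gene_id[!out$ambiguous])) {
    idx <- which(!out$ambiguous & out$gene_id == g)
    strand <- out$strand[idx][1]
    out$rank_5to3[idx] <- rank_positions(out$start[idx], strand)
    out$bin_id[idx] <- sprintf("%s:E%03d", g, out$rank_5to3[idx])
  }
  amb <- which(out$ambiguous)
  if (length(amb)) {
    out$bin_id[amb] <- sprintf("%s:A%03d", out$gene_ids[amb], seq_along(amb))
  }
  out <- out[, c("bin_id", "gene_id", "gene_ids", "chrom", "start", "end",
                 "strand", "rank_5to3", "ambiguous")]
  class(out) <- c("exon_bins", "data.frame")
  out
}

# 5'->3' rank of genomically sorted starts: leftmost first on '+', reversed on '-'.
rank_positions <- function(starts, strand) {
  r <- rank(starts, ties.method = "first")
  if (strand == "-") r <- length(r) + 1L - r
  as.integer(r)
}

#' Assign strand-aware 5' to 3' ranks to the bins of one gene
#'
#' @param bins data.frame with `start` and `gene_id`/`gene_ids` columns, all
#'   belonging to a single gene.
#' @param strand `"+"` or `"-"`.
#' @return `bins` with `rank_5to3` filled in; rank 1 is the 5'-most bin.
#' @export
order_bins <- function(bins, strand) {
  gids <- unique(bins$gene_id[!is.na(bins$gene_id)])
  if (length(gids) > 1L) stop("order_bins: bins from more than one gene")
  bins$rank_5to3 <- rank_positions(bins$start, strand)
  bins
}

as_exon_records <- function(x) {
  if (is.data.frame(x)) {
    need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
    miss <- setdiff(need, names(x))
    if (length(miss)) stop("missing exon record columns: ", paste(miss, collapse = ", "))
    return(x[, need])
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "transcript_model"))) {
    return(do.call(rbind, lapply(x, function(t) {
      data.frame(gene_id = t$gene_id, transcript_id = t$transcript_id,
                 chrom = t$chrom, strand = t$strand,
                 start = t$exons$start, end = t$exons$end,
                 stringsAsFactors = FALSE)
    })))
  }
  stop("x must be a list of transcript_model objects or an exon record data.frame")
}

#' Read gene models from a GTF file
#'
#' Uses `rtracklayer` to parse the GTF (1-based inclusive coordinates,
#' converted to the package's 0-based half-open convention) and, optionally,
#' attaches spliced transcript sequences from a FASTA of transcript sequences.
#'
#' @param gtf path to a GTF whose exon features carry `gene_id` and
#'   `transcript_id` attributes.
#' @param transcript_fasta optional path to a transcript FASTA (DNA alphabet;
#'   read back as RNA) whose names are transcript ids.
#' @return list of [transcript_model()] objects.
#' @export
read_gene_models <- function(gtf, transcript_fasta = NULL) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", gtf)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id)) {
    stop("GTF exon features must carry gene_id and transcript_id attributes")
  }
  seqs <- NULL
  if (!is.null(transcript_fasta)) {
    fa <- Biostrings::readDNAStringSet(transcript_fasta)
    seqs <- stats::setNames(as.character(fa), names(fa))
  }
  models <- lapply(split(seq_along(gr), gr$transcript_id), function(i) {
    sub <- gr[i]
    tid <- sub$transcript_id[1]
    sq <- if (!is.null(seqs)) seqs[[tid]] else NULL
    transcript_model(
      gene_id = sub$gene_id[1], transcript_id = tid,
      chrom = as.character(GenomicRanges::seqnames(sub))[1],
      strand = as.character(GenomicRanges::strand(sub))[1],
      exons = data.frame(start = GenomicRanges::start(sub) - 1L,
                         end = GenomicRanges::end(sub)),
      sequence = sq
    )
  })
  unname(models)
}

#' Write flattened bins as a TSV
#' @param bins an `"exon_bins"` data.frame.
#' @param path output file.
#' @export
write_bins_tsv <- function(bins, path) {
  write_atomic(function(p) {
    utils::write.table(as.data.frame(bins), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

#' @rdname write_bins_tsv
#' @export
read_bins_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("exon_bins", "data.frame")
  out
}
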