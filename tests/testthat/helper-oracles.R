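# Independent brute-force oracles used to validate the fast implementations.

# Per-base membership flattening oracle: walks every base of a (small) locus,
# records the set of (gene, transcript) memberships covering it, and merges
# maximal runs of constant non-empty membership into bins.
oracle_flatten <- function(records) {
  out <- NULL
  for (chrom in unique(records$chrom)) {
    rec <- records[records$chrom == chrom, ]
    lo <- min(rec$start)
    hi <- max(rec$end)
    memb_at <- function(b) {
      i <- which(rec$start <= b & b < rec$end)
      if (length(i) == 0) return("")
      paste(sort(unique(paste(rec$gene_id[i], rec$transcript_id[i], sep = "\t"))),
            collapse = "\n")
    }
    membs <- vapply(lo:(hi - 1), memb_at, character(1))
    runs <- rle(membs)
    ends <- lo + cumsum(runs$lengths)
    starts <- c(lo, ends[-length(ends)])
    keep <- nzchar(runs$values)
    genes <- vapply(strsplit(runs$values[keep], "\n"), function(m) {
      paste(sort(unique(vapply(strsplit(m, "\t"), `[[`, character(1), 1))),
            collapse = "+")
    }, character(1))
    out <- rbind(out, data.frame(
      chrom = chrom, start = starts[keep], end = ends[keep],
      gene_ids = genes, ambiguous = grepl("+", genes, fixed = TRUE),
      stringsAsFactors = FALSE))
  }
  out[order(out$chrom, out$start), ]
}

# Random multi-isoform toy locus for flattening tests: a few genes, each with
# 1-3 transcripts of random exons on a <= 10 kb region; overlaps (within and
# across genes) arise naturally.
random_locus <- function(n_genes = 3) {
  rec <- NULL
  for (g in seq_len(n_genes)) {
    origin <- sample.int(5000, 1)
    for (tr in seq_len(sample.int(3, 1))) {
      n_ex <- sample(1:4, 1)
      starts <- sort(origin + sample.int(3000, n_ex))
      widths <- sample(20:300, n_ex, replace = TRUE)
      # trim overlaps within the transcript
      for (i in seq_len(n_ex - 1)) {
        widths[i] <- min(widths[i], starts[i + 1] - starts[i])
      }
      widths <- pmax(widths, 1L)
      rec <- rbind(rec, data.frame(
        gene_id = sprintf("g%d", g), transcript_id = sprintf("g%d.t%d", g, tr),
        chrom = "chrT", strand = "+", start = starts, end = starts + widths,
        stringsAsFactors = FALSE))
    }
  }
  rec
}

# Exhaustive hairpin enumeration oracle over all (loop start a, loop length l,
# stem length s) tuples; same scoring and tie order as fold_hairpin.
oracle_fold <- function(seq, match_pos, window = 30, min_stem = 4,
                        loop_range = c(4, 12)) {
  x <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  n <- length(x)
  score <- c("GC" = -3, "CG" = -3, "AU" = -2, "UA" = -2, "GU" = -1, "UG" = -1)
  g_pos <- match_pos + 2L
  lo <- max(1L, match_pos - window)
  hi <- min(n, match_pos + 5L + window)
  best <- NULL
  for (a in lo:g_pos) {
    for (l in loop_range[1]:loop_range[2]) {
      if (a + l - 1L < g_pos || a + l - 1L > hi) next
      for (s in min_stem:((hi - lo + 1) %/% 2)) {
        i <- a - s
        j <- a + l + s - 1L
        if (i < lo || j > hi) break
        pr <- score[paste0(x[i:(a - 1L)], x[(j):(a + l)])]
        if (anyNA(pr)) break
        e <- sum(pr) + 0.5 * max(0, l - 4)
        if (is.null(best) || e < best$energy - 1e-12) {
          best <- list(energy = e, loop_start = a, loop_len = l, stem_len = s)
        }
      }
    }
  }
  best
}

# Closed-form G-test of independence on a 2x2 table.
g_test_2x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(tab * log(tab / e), na.rm = TRUE)
}

# Direct two-segment RSS search (independent of the cumsum implementation).
oracle_changepoint <- function(v) {
  n <- length(v)
  best <- NULL
  for (k in 1:(n - 1)) {
    a <- v[1:k]
    b <- v[(k + 1):n]
    rss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(k = k, rss = rss, delta = mean(a) - mean(b))
    }
  }
  best
}

# Small deterministic two-condition count matrix builder for DEU tests.
toy_matrix <- function(counts, n_mock = 3, n_ire1 = 3, gene = "G1") {
  nb <- nrow(counts)
  bins <- data.frame(
    bin_id = sprintf("%s:E%03d", gene, seq_len(nb)), gene_id = gene,
    gene_ids = gene, chrom = "chrT", start = (seq_len(nb) - 1L) * 100L,
    end = seq_len(nb) * 100L, strand = "+", rank_5to3 = seq_len(nb),
    ambiguous = FALSE, stringsAsFactors = FALSE)
  class(bins) <- c("exon_bins", "data.frame")
  exon_count_matrix(counts, bins, rep(c("mock", "ire1"), c(n_mock, n_ire1)))
}
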