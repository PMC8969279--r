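#' Simulate a toy transcriptome
#'
#' Generates `n_genes` single-isoform genes laid end to end (with gaps) on one
#' synthetic chromosome, with random strand, exon count and exon lengths drawn
#' uniformly from the given ranges, and i.i.d. spliced sequences at the given
#' GC fraction. Hairpins are planted afterwards with
#' [plant_cleavage_hairpin()], which substitutes bases in place.
#'
#' @param n_genes number of genes (>= 1).
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_len integer range `c(min, max)` of exon lengths (nt).
#' @param gc GC fraction of the simulated sequence, in (0, 1).
#' @param intron_len integer range of intron lengths (nt).
#' @param seed integer seed; identical seeds give identical output.
#' @return list of [transcript_model()] objects with unique gene/transcript ids.
#' @export
simulate_transcriptome <- function(n_genes, exons_per_gene = c(5, 8),
                                   exon_len = c(80, 200), gc = 0.5,
                                   intron_len = c(100, 1000), seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  check_range <- function(r, name) {
    if (length(r) != 2 || any(r < 1) || r[2] < r[1]) {
      stop("invalid range for ", name)
    }
  }
  check_range(exons_per_gene, "exons_per_gene")
  check_range(exon_len, "exon_len")
  check_range(intron_len, "intron_len")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  with_seed(seed, {
    cursor <- 0L
    # sample() on a length-1 vector would sample from 1:x; index explicitly
    sample_range <- function(r, n) {
      seq(r[1], r[2])[sample.int(r[2] - r[1] + 1L, n, replace = TRUE)]
    }
    lapply(seq_len(n_genes), function(i) {
      n_ex <- sample_range(exons_per_gene, 1)
      widths <- sample_range(exon_len, n_ex)
      gaps <- sample_range(intron_len, n_ex)
      starts <- cursor + cumsum(gaps) + c(0L, cumsum(widths[-n_ex]))
      cursor <<- starts[n_ex] + widths[n_ex]
      strand <- sample(c("+", "-"), 1)
      seq <- paste(sample(RNA_BASES, sum(widths), replace = TRUE,
                          prob = base_prob), collapse = "")
      transcript_model(
        gene_id = sprintf("G%04d", i),
        transcript_id = sprintf("G%04d.T1", i),
        chrom = "chrS", strand = strand,
        exons = data.frame(start = starts, end = starts + widths),
        sequence = seq
      )
    })
  })
}

#' Plant an XBP1-like cleavage hairpin into a transcript
#'
#' Substitutes (never inserts, so coordinates stay stable) a perfect hairpin
#' into the spliced sequence: a 5' stem of `stem_len` bases, the `loop`
#' (which must contain exactly one CUGCAG consensus), and the reverse
#' complement of the stem. The hairpin is positioned so that the guanine at
#' consensus position 3 -- the base 3' of which IRE1 cleaves (CUG|CAG) -- sits
#' exactly at transcript coordinate `position`.
#'
#' @param t a [transcript_model()] with a sequence.
#' @param position 1-based transcript coordinate of the cleavage guanine.
#' @param stem_len stem length in base pairs (default 6).
#' @param loop loop sequence containing exactly one CUGCAG (default
#'   `"ACUGCAG"`, a 7-nt loop).
#' @param stem 5' stem sequence of length `stem_len` (default alternating GC).
#' @return list with elements `model` (modified transcript) and `site`
#'   (data.frame with `gene_id`, `transcript_id`, `position`).
#' @export
plant_cleavage_hairpin <- function(t, position, stem_len = 6,
                                   loop = "ACUGCAG", stem = NULL) {
  n_hits <- length(scan_consensus(loop))
  if (n_hits != 1L) stop("loop must contain exactly one CUGCAG")
  if (is.null(stem)) {
    stem <- paste(rep_len(c("G", "C"), stem_len), collapse = "")
  }
  if (nchar(stem) != stem_len) stop("stem length must equal stem_len")
  g_in_loop <- scan_consensus(loop) + 2L       # guanine at consensus position 3
  window <- paste0(stem, loop, rna_revcomp(stem))
  wlen <- nchar(window)
  wstart <- position - stem_len - g_in_loop + 1L   # transcript coord of window base 1
  len <- transcript_length(t)
  if (wstart < 1L || wstart + wlen - 1L > len) {
    stop(sprintf("hairpin window [%d, %d] outside transcript [1, %d]",
                 wstart, wstart + wlen - 1L, len))
  }
  seq <- t$sequence
  substr(seq, wstart, wstart + wlen - 1L) <- window
  t$sequence <- seq
  list(model = t,
       site = data.frame(gene_id = t$gene_id, transcript_id = t$transcript_id,
                         position = position, stringsAsFactors = FALSE))
}

#' Simulation ground truth
#'
#' Records which genes are RIDD targets, where they are cleaved, with what
#' efficiency, and the nuisance parameters of the count model.
#'
#' @param models list of [transcript_model()] objects.
#' @param sites data.frame with columns `gene_id`, `position` (1-based
#'   transcript coordinate; cleavage occurs 3' of this base). Empty for a null
#'   simulation.
#' @param epsilon cleavage efficiency in `[0, 1]`: the fraction of molecules
#'   cleaved, i.e. the expected read loss 5' of the site. Scalar (applied to
#'   all target genes) or named by gene id. Non-target genes have epsilon 0.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   `mu + alpha mu^2`); 0 degenerates to Poisson.
#' @param library_sizes optional positive per-sample scale factors; drawn by
#'   [simulate_counts()] when NULL.
#' @param seed seed recorded for provenance.
#' @return object of class `"sim_truth"`.
#' @export
sim_truth <- function(models, sites = NULL, epsilon = 0.85, dispersion = 0.05,
                      library_sizes = NULL, seed = NA_integer_) {
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  if (is.null(sites)) {
    sites <- data.frame(gene_id = character(0), position = integer(0))
  }
  if (!all(sites$gene_id %in% gene_ids)) {
    stop("cleavage sites refer to genes absent from the models")
  }
  lens <- stats::setNames(vapply(models, transcript_length, numeric(1)), gene_ids)
  if (any(sites$position < 1 | sites$position >= lens[sites$gene_id])) {
    stop("cleavage positions must lie strictly inside the transcript")
  }
  if (any(epsilon < 0 | epsilon > 1)) stop("epsilon must be in [0, 1]")
  is_target <- gene_ids %in% sites$gene_id
  eps <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  if (length(epsilon) == 1L && is.null(names(epsilon))) {
    eps[is_target] <- epsilon
  } else {
    eps[names(epsilon)] <- epsilon
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(
    list(genes = data.frame(gene_id = gene_ids, is_target = is_target,
                            epsilon = unname(eps[gene_ids]),
                            stringsAsFactors = FALSE),
         sites = sites, dispersion = dispersion,
         library_sizes = library_sizes, seed = seed),
    class = "sim_truth"
  )
}

#' Expected bin means under the poly(A)-selection read-loss model
#'
#' The mock mean of bin `i` of gene `g` in sample `j` is
#' `s_j * depth * lambda_g * len_i / sum(lambda * len)` (library size x gene
#' abundance x within-gene weight proportional to bin length). In IRE1-treated
#' samples a bin entirely 5' of a cleavage site is multiplied by
#' `1 - epsilon_g`; a bin containing the site is scaled by the fraction of its
#' length 3' of the site plus `(1 - epsilon_g)` times the 5' fraction; bins 3'
#' of every site are untouched. With several sites per gene the per-site
#' factors multiply (a 5' fragment survives only if uncut at every downstream
#' site).
#'
#' @param models,truth see [simulate_counts()].
#' @param bins flattened bins for `models`.
#' @param lambda named per-gene abundances.
#' @param library_sizes named per-sample scale factors.
#' @param condition per-sample labels.
#' @param depth expected total reads in a library-size-1 sample.
#' @return matrix of expected counts, bins x samples.
#' @keywords internal
expected_bin_means <- function(models, truth, bins, lambda, library_sizes,
                               condition, depth) {
  model_by_gene <- stats::setNames(models, vapply(models, `[[`, character(1), "gene_id"))
  binlen <- bins$end - bins$start
  # base weight: sum over member genes of lambda_g * length
  base_w <- numeric(nrow(bins))
  scale_ire1 <- numeric(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    genes <- strsplit(bins$gene_ids[b], "+", fixed = TRUE)[[1]]
    w <- 0
    w_treated <- 0
    for (g in genes) {
      t <- model_by_gene[[g]]
      wg <- lambda[[g]] * binlen[b]
      tiv <- bin_transcript_interval(t, bins$start[b], bins$end[b])
      sc <- 1
      sites <- truth$sites[truth$sites$gene_id == g, , drop = FALSE]
      epsg <- truth$genes$epsilon[truth$genes$gene_id == g]
      for (p in sites$position) {
        frac5 <- max(0, min(tiv[2], p) - tiv[1] + 1) / (tiv[2] - tiv[1] + 1)
        sc <- sc * ((1 - frac5) + (1 - epsg) * frac5)
      }
      w <- w + wg
      w_treated <- w_treated + wg * sc
    }
    base_w[b] <- w
    scale_ire1[b] <- if (w > 0) w_treated / w else 1
  }
  total_w <- sum(base_w)
  mu <- outer(base_w / total_w * depth, library_sizes)
  treat <- condition == "ire1"
  mu[, treat] <- mu[, treat] * scale_ire1
  dimnames(mu) <- list(bins$bin_id, names(library_sizes))
  mu
}

# Transcript-coordinate interval (1-based inclusive, 5'->3') of a genomic
# sub-interval of an exon of t.
bin_transcript_interval <- function(t, gstart, gend) {
  a <- genomic_to_transcript(t, gstart)
  b <- genomic_to_transcript(t, gend - 1L)
  c(min(a, b), max(a, b))
}

#' Simulate replicate exon counts for an IRE1 cleavage assay
#'
#' Draws negative-binomial counts for `n_mock` mock and `n_ire1` IRE1-treated
#' replicates under the mean model of [expected_bin_means()]: cleaved
#' transcripts lose coverage 5' of the cleavage site in proportion to the
#' cleavage efficiency, emulating loss of the non-polyadenylated 5' fragment
#' during poly(A) selection.
#'
#' @param models list of [transcript_model()] objects.
#' @param truth a [sim_truth()] for these models.
#' @param n_mock,n_ire1 replicates per condition (>= 2).
#' @param depth expected reads per sample at library size 1.
#' @param seed integer seed.
#' @return an [exon_count_matrix()]; attributes `means` (expected counts),
#'   `lambda` (per-gene abundances) and `library_sizes` record the generating
#'   model for testing.
#' @export
simulate_counts <- function(models, truth, n_mock = 3, n_ire1 = 3,
                            depth = 1e6, seed = NULL) {
  if (n_mock < 2 || n_ire1 < 2) stop("at least 2 replicates per condition")
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  if (!identical(truth$genes$gene_id, gene_ids)) {
    stop("truth does not match the supplied models")
  }
  bins <- flatten_gene_models(models)
  with_seed(seed, {
    lambda <- stats::setNames(stats::rlnorm(length(models), meanlog = 4, sdlog = 1),
                              gene_ids)
    condition <- rep(c("mock", "ire1"), c(n_mock, n_ire1))
    samples <- paste0(condition, "_", c(seq_len(n_mock), seq_len(n_ire1)))
    lib <- truth$library_sizes
    if (is.null(lib)) {
      lib <- stats::rlnorm(length(samples), meanlog = 0, sdlog = 0.15)
      lib <- lib / geomean(lib)
    }
    lib <- stats::setNames(lib, samples)
    mu <- expected_bin_means(models, truth, bins, lambda, lib, condition, depth)
    alpha <- truth$dispersion
    counts <- if (alpha > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / alpha), nrow = nrow(mu))
    } else {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    }
    dimnames(counts) <- dimnames(mu)
    m <- exon_count_matrix(counts, bins, condition)
    attr(m, "means") <- mu
    attr(m, "lambda") <- lambda
    attr(m, "library_sizes") <- lib
    m
  })
}

#' Simulate a complete RIDD discovery experiment
#'
#' Convenience wrapper: simulates a transcriptome, picks `n_targets` target
#' genes, plants one XBP1-like hairpin per target a few bases into its second
#' exon (so the depleted 5' segment is the first exon bin and the cleavage
#' site lies within the localization window), builds the ground truth, and
#' draws counts.
#'
#' @inheritParams simulate_transcriptome
#' @inheritParams simulate_counts
#' @param n_targets number of cleaved genes.
#' @param epsilon cleavage efficiency of the targets.
#' @param dispersion NB dispersion alpha.
#' @param site_offset cleavage guanine position, measured from the start of
#'   the second exon (default 15 nt).
#' @return list of class `"ridd_simulation"` with elements `models`, `truth`,
#'   `counts`.
#' @export
simulate_ridd_experiment <- function(n_genes = 200, n_targets = 20,
                                     epsilon = 0.85, dispersion = 0.05,
                                     n_mock = 3, n_ire1 = 3, depth = 1e6,
                                     exons_per_gene = c(5, 8),
                                     exon_len = c(80, 200), gc = 0.5,
                                     site_offset = 15, seed = 1) {
  if (n_targets > n_genes) stop("n_targets cannot exceed n_genes")
  with_seed(seed, {
    models <- simulate_transcriptome(n_genes, exons_per_gene = exons_per_gene,
                                     exon_len = exon_len, gc = gc, seed = NULL)
    target_idx <- sort(sample.int(n_genes, n_targets))
    sites <- NULL
    for (i in target_idx) {
      t <- models[[i]]
      ex_len <- t$exons$end - t$exons$start
      if (t$strand == "-") ex_len <- rev(ex_len)        # transcript order
      pos <- ex_len[1] + site_offset
      planted <- plant_cleavage_hairpin(t, pos)
      models[[i]] <- planted$model
      sites <- rbind(sites, planted$site)
    }
    truth <- sim_truth(models, sites = sites[, c("gene_id", "position")],
                       epsilon = epsilon, dispersion = dispersion, seed = seed)
    counts <- simulate_counts(models, truth, n_mock = n_mock, n_ire1 = n_ire1,
                              depth = depth, seed = NULL)
    structure(list(models = models, truth = truth, counts = counts),
              class = "ridd_simulation")
  })
}

#' @export
print.ridd_simulation <- function(x, ...) {
  cat(sprintf("<ridd_simulation> %d genes (%d targets), %d bins x %d samples\n",
              nrow(x$truth$genes), sum(x$truth$genes$is_target),
              nrow(x$counts$counts), ncol(x$counts$counts)))
  invisible(x)
}

#' Write simulated transcripts as FASTA
#'
#' Sequences are written in the DNA alphabet (U is converted to T on write, as
#' in reference transcriptome FASTA files) under their transcript ids;
#' [read_gene_models()] converts back to RNA on read.
#'
#' @param models list of [transcript_model()] objects.
#' @param path output path.
#' @export
write_transcripts_fasta <- function(models, path) {
  seqs <- vapply(models, function(t) gsub("U", "T", t$sequence, fixed = TRUE),
                 character(1))
  names(seqs) <- vapply(models, `[[`, character(1), "transcript_id")
  write_atomic(function(p) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), p)
  }, path)
}

#' Write gene models as GTF
#'
#' One `exon` feature per exon with `gene_id` and `transcript_id` attributes,
#' 1-based inclusive coordinates as required by the format.
#'
#' @param models list of [transcript_model()] objects.
#' @param path output path.
#' @export
write_gene_models_gtf <- function(models, path) {
  rec <- as_exon_records(models)
  gr <- GenomicRanges::GRanges(
    rec$chrom, IRanges::IRanges(rec$start + 1L, rec$end), strand = rec$strand)
  gr$source <- "riddseq"
  gr$type <- "exon"
  gr$gene_id <- rec$gene_id
  gr$transcript_id <- rec$transcript_id
  write_atomic(function(p) rtracklayer::export(gr, p, format = "gtf"), path)
}

#' Write / read simulation ground truth as JSON
#' @param truth a [sim_truth()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(seed = truth$seed, dispersion = truth$dispersion,
              library_sizes = truth$library_sizes,
              genes = truth$genes, sites = truth$sites)
  write_atomic(function(p) {
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(genes = as.data.frame(obj$genes),
         sites = as.data.frame(obj$sites),
         dispersion = obj$dispersion,
         library_sizes = obj$library_sizes,
         seed = obj$seed),
    class = "sim_truth"
  )
}
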