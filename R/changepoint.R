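#' Build a 5' to 3' depletion profile for one gene
#'
#' Maps each testable bin's signed usage fold change onto the log2 ratio scale
#' (`fc < 0` becomes `-log2(|fc|)`, `fc > 0` becomes `log2(fc)`), ordered by
#' 5' to 3' rank. A cleaved transcript shows a step: depressed values 5' of
#' the cleavage site, values near zero 3' of it.
#'
#' @param gene_results rows of a `"deu_result"` for one gene.
#' @param fdr_max significance threshold recorded per bin (default 0.05).
#' @return object of class `"depletion_profile"`: list with `gene_id`,
#'   `rank` (bin ranks), `bin_id`, `value` (log2 scale), `sig` (fdr < fdr_max),
#'   and, after [localize_changepoint()] / [classify_xbp1_like()],
#'   `changepoint`, `depth_delta`, `xbp1_like`. Untestable genes give an empty
#'   profile (zero bins).
#' @export
build_profile <- function(gene_results, fdr_max = 0.05) {
  g <- unique(gene_results$gene_id)
  if (length(g) != 1L) stop("build_profile expects the bins of exactly one gene")
  d <- gene_results[gene_results$testable & !is.na(gene_results$fc), , drop = FALSE]
  d <- d[order(d$rank_5to3), , drop = FALSE]
  structure(
    list(gene_id = g, rank = d$rank_5to3, bin_id = d$bin_id,
         value = sign(d$fc) * log2(abs(d$fc)),
         sig = !is.na(d$fdr) & d$fdr < fdr_max,
         changepoint = NA_integer_, depth_delta = NA_real_, xbp1_like = FALSE),
    class = "depletion_profile"
  )
}

#' @export
print.depletion_profile <- function(x, ...) {
  cat(sprintf("<depletion_profile> %s: %d bins, changepoint %s, delta %.2f, xbp1_like %s\n",
              x$gene_id, length(x$value),
              ifelse(is.na(x$changepoint), "none", x$changepoint),
              x$depth_delta, x$xbp1_like))
  invisible(x)
}

#' Localize the cleavage change-point of a profile
#'
#' Fits every two-segment split of the profile (bins `1..k` vs `k+1..n`,
#' `1 <= k < n`) by least squares and returns the `k` minimizing the residual
#' sum of squares, with ties broken toward the smallest `k` -- the 5'-most
#' boundary, since the depleted run is anchored at the transcript start under
#' poly(A) selection. `depth_delta` is mean(5' segment) - mean(3' segment);
#' for a cleaved gene it is strongly negative.
#'
#' @param profile a `"depletion_profile"` or bare numeric vector of per-bin
#'   log2 values (>= 2 bins).
#' @return list `(k, depth_delta)`; a `"depletion_profile"` input is returned
#'   with the fields filled in.
#' @export
localize_changepoint <- function(profile) {
  v <- if (inherits(profile, "depletion_profile")) profile$value else as.numeric(profile)
  n <- length(v)
  if (n < 2) stop("change-point localization needs at least 2 bins")
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  ks <- seq_len(n - 1)
  m1 <- cs[ks] / ks
  m2 <- (cs[n] - cs[ks]) / (n - ks)
  rss <- (cs2[ks] - cs[ks]^2 / ks) +
    ((cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / (n - ks))
  k <- which(rss <= min(rss) + 1e-12)[1]          # tie-break: smallest k
  out <- list(k = as.integer(k), depth_delta = m1[k] - m2[k])
  if (inherits(profile, "depletion_profile")) {
    profile$changepoint <- out$k
    profile$depth_delta <- out$depth_delta
    return(profile)
  }
  out
}

#' Classify a profile as XBP1-like
#'
#' A gene is called XBP1-like -- i.e. its usage profile resembles the known
#' IRE1 substrate XBP1: depleted 5' of a point, unaffected 3' of it -- when
#' all three hold at the fitted change-point:
#' * the segment-mean difference `depth_delta <= -min_delta` (default 1 log2,
#'   a two-fold usage drop);
#' * at least `min_5p_sig_fraction` of 5'-segment bins are significant
#'   (default half);
#' * the 3' segment is flat: `|mean(3' segment)| <= max_3p_depletion`
#'   (default 0.5 log2). This clause distinguishes cleavage from
#'   whole-transcript downregulation, which depresses every bin.
#'
#' @param profile a `"depletion_profile"` with changepoint computed.
#' @param min_delta,min_5p_sig_fraction,max_3p_depletion thresholds as above.
#' @return the profile with `xbp1_like` set.
#' @export
classify_xbp1_like <- function(profile, min_delta = 1.0,
                               min_5p_sig_fraction = 0.5,
                               max_3p_depletion = 0.5) {
  stopifnot(inherits(profile, "depletion_profile"))
  if (is.na(profile$changepoint)) stop("run localize_changepoint first")
  k <- profile$changepoint
  v <- profile$value
  m3 <- mean(v[(k + 1):length(v)])
  profile$xbp1_like <-
    (profile$depth_delta <= -min_delta) &&
    (mean(profile$sig[seq_len(k)]) >= min_5p_sig_fraction) &&
    (abs(m3) <= max_3p_depletion)
  profile
}

#' Transcript-coordinate window around the cleavage change-point
#'
#' Maps the junction between bin `k` and bin `k+1` (the 3' end of the last
#' depleted bin) to transcript coordinates and widens it by `pad` nucleotides
#' each side, clipped to the transcript. This window is handed to the
#' stem-loop scanner.
#'
#' @param profile a classified `"depletion_profile"` with `xbp1_like = TRUE`.
#' @param bins the gene's `"exon_bins"` rows.
#' @param t the gene's [transcript_model()].
#' @param pad half-width in nt (default 100).
#' @return data.frame with `gene_id`, `transcript_id`, `start`, `end`
#'   (1-based inclusive transcript coordinates) and `junction`.
#' @export
cleavage_window <- function(profile, bins, t, pad = 100) {
  stopifnot(inherits(profile, "depletion_profile"))
  if (!isTRUE(profile$xbp1_like)) stop("cleavage_window requires an XBP1-like profile")
  k <- profile$changepoint
  bin_k <- bins[match(profile$bin_id[k], bins$bin_id), ]
  # genomic base at the 3' end of bin k, strand-aware
  gpos <- if (t$strand == "+") bin_k$end - 1L else bin_k$start
  junction <- tryCatch(genomic_to_transcript(t, gpos), error = function(e) {
    warning("junction not exonic in transcript ", t$transcript_id,
            "; using nearest exonic coordinate")
    nearest_exonic_tpos(t, gpos)
  })
  len <- transcript_length(t)
  data.frame(gene_id = profile$gene_id, transcript_id = t$transcript_id,
             start = max(1L, junction - as.integer(pad)),
             end = min(len, junction + as.integer(pad)),
             junction = junction, stringsAsFactors = FALSE)
}

# Transcript coordinate of the exonic base closest to a genomic position.
nearest_exonic_tpos <- function(t, gpos) {
  ex <- t$exons
  cand <- unlist(mapply(function(s, e) c(s, e - 1L), ex$start, ex$end))
  g <- cand[which.min(abs(cand - gpos))]
  genomic_to_transcript(t, g)
}

#' Cleavage-window BED6 output
#'
#' One line per window with the transcript id as chromosome, 0-based half-open
#' coordinates, the gene as name and `-depth_delta * 100` (clipped to 0..1000)
#' as score.
#'
#' @param windows data.frame from [cleavage_window()].
#' @param deltas per-window depth_delta values (log2).
#' @param path output file.
#' @export
write_windows_bed <- function(windows, deltas, path) {
  score <- pmin(1000L, pmax(0L, as.integer(round(-deltas * 100))))
  df <- data.frame(windows$transcript_id, windows$start - 1L, windows$end,
                   windows$gene_id, score, ".")
  write_atomic(function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }, path)
}
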