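#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median of its
#' count ratios to the geometric-mean pseudo-reference, computed over bins
#' with all-positive counts, then rescaled so the factors have geometric
#' mean 1. If no bin has all-positive counts the total-count ratio is used
#' instead (with a warning).
#'
#' @param m an [exon_count_matrix()] or a bare count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "exon_count_matrix")) m$counts else as.matrix(m)
  if (all(counts == 0)) stop("all-zero count matrix")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    sub <- counts[pos, , drop = FALSE]
    ref <- apply(sub, 1, geomean)
    sf <- apply(sub / ref, 2, stats::median)
  } else {
    warning("no bin with all-positive counts; falling back to total-count ratios")
    tot <- colSums(counts)
    sf <- tot / geomean(tot)
  }
  sf <- sf / geomean(sf)
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion per bin
#'
#' On size-factor-normalized counts, estimates for each bin
#' `alpha = max(0, (s2 - mu) / mu^2)` where `mu` is the mean and `s2` the
#' within-condition pooled variance, then shrinks each estimate halfway toward
#' the gene-wise mean dispersion. Degenerate data (zero mean or
#' variance <= mean) gives 0, never an error.
#'
#' With only a handful of replicates the per-bin estimate is noisy, and noisy
#' plug-in dispersions make the likelihood-ratio test anti-conservative
#' (underestimates inflate the statistic more than overestimates deflate it).
#' `prior` lets the caller stabilize the shrinkage target: the gene-wise mean
#' is then averaged with the supplied value (typically the experiment-wide
#' mean raw dispersion) before the per-bin shrinkage. [deu_test()] does this
#' automatically.
#'
#' @param gene_counts count matrix of one gene's bins x samples.
#' @param sf per-sample size factors.
#' @param condition per-sample labels.
#' @param prior optional dispersion the gene-wise target is averaged with.
#' @return per-bin dispersion alpha >= 0.
#' @export
estimate_dispersion <- function(gene_counts, sf, condition, prior = NULL) {
  raw <- raw_dispersion(gene_counts, sf, condition)
  target <- if (is.null(prior)) mean(raw) else 0.5 * mean(raw) + 0.5 * prior
  0.5 * raw + 0.5 * target
}

# Per-bin method-of-moments dispersion on normalized counts: variance pooled
# within condition, max(0, (s2 - mu) / mu^2).
raw_dispersion <- function(gene_counts, sf, condition) {
  x <- sweep(as.matrix(gene_counts), 2, sf, "/")
  cond <- as.character(condition)
  n <- ncol(x)
  ncond <- length(unique(cond))
  apply(x, 1, function(row) {
    mu <- mean(row)
    if (mu <= 0) return(0)
    ss <- sum(unlist(lapply(split(row, cond), function(r) (r - mean(r))^2)))
    s2 <- ss / (n - ncond)
    max(0, (s2 - mu) / mu^2)
  })
}

#' Likelihood-ratio test for differential usage of one bin
#'
#' Fits negative-binomial log-linear models (fixed plug-in dispersion) to the
#' counts of the bin and of the rest of its gene across samples. The null
#' model has sample and part (bin vs rest) effects; the alternative adds a
#' condition-by-part interaction. The statistic is `2 * (l1 - l0)`, referred
#' to chi-squared with 1 df. With `alpha = 0` the fit is Poisson and, on a
#' collapsed 2x2 table with equal size factors, the statistic equals the
#' G-test of independence.
#'
#' The two parts may carry different dispersions: the "rest" counts are a sum
#' over the gene's other bins, and a sum of k NB variables with dispersion
#' `alpha` has dispersion about `alpha / k`, so plugging the bin's dispersion
#' into the aggregate would overstate its variance and make the test
#' conservative. Pass `alpha = c(bin, rest)` to use part-specific values (as
#' [deu_test()] does); a scalar is applied to both parts.
#'
#' @param bin_counts integer vector, the bin's counts per sample.
#' @param rest_counts integer vector, summed counts of the gene's other bins.
#' @param condition per-sample labels (`"mock"`/`"ire1"`, >= 2 each).
#' @param alpha NB dispersion: scalar, or `c(bin, rest)`.
#' @param sf per-sample size factors (used for the usage fractions).
#' @return list with `lr_stat`, `p`, `usage_mock`, `usage_ire1`, `fc`,
#'   `pseudocount` (TRUE when degenerate usages required the 0.5 pseudocount).
#' @export
test_bin <- function(bin_counts, rest_counts, condition, alpha, sf) {
  condition <- as.character(condition)
  n <- length(bin_counts)
  stopifnot(length(rest_counts) == n, length(condition) == n, length(sf) == n)
  if (min(table(condition)) < 2) stop("need >= 2 replicates per condition")
  if (length(alpha) == 1L) alpha <- c(alpha, alpha)

  usage <- usage_fractions(bin_counts, rest_counts, condition, sf)

  if (all(bin_counts == 0)) {
    return(list(lr_stat = 0, p = 1, usage_mock = usage$mock,
                usage_ire1 = usage$ire1, fc = NA_real_,
                pseudocount = usage$pseudocount))
  }
  y <- c(bin_counts, rest_counts)
  alpha_obs <- rep(alpha, each = n)
  part_bin <- rep(c(1, 0), each = n)
  samp <- diag(n)[rep(seq_len(n), 2), , drop = FALSE]
  inter <- part_bin * rep(as.numeric(condition == "ire1"), 2)
  X0 <- cbind(samp, part_bin)
  X1 <- cbind(X0, inter)
  ll0 <- nb_fit_loglik(y, X0, alpha_obs)
  ll1 <- nb_fit_loglik(y, X1, alpha_obs)
  lr <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  list(lr_stat = lr, p = p, usage_mock = usage$mock, usage_ire1 = usage$ire1,
       fc = fold_change(usage$mock, usage$ire1),
       pseudocount = usage$pseudocount)
}

# Maximized NB log-likelihood of a log-linear model with fixed per-observation
# dispersion, by iteratively reweighted least squares (weights mu/(1+alpha mu),
# the Fisher weights of the log link). alpha near 0 degenerates to Poisson.
nb_fit_loglik <- function(y, X, alpha_obs) {
  beta <- qr.solve(qr(X), log(y + 0.5))
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha_obs * mu)
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    beta_new <- qr.solve(qr(X * sw), z * sw)
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- pmax(exp(drop(X %*% beta)), 1e-10)
  pois <- alpha_obs < 1e-10
  sum(stats::dpois(y[pois], mu[pois], log = TRUE)) +
    sum(stats::dnbinom(y[!pois], mu = mu[!pois], size = 1 / alpha_obs[!pois],
                       log = TRUE))
}

# Normalized bin-vs-rest usage fraction per condition; 0.5 pseudocount applied
# to the counts when a fraction would otherwise be 0 or 1.
usage_fractions <- function(bin_counts, rest_counts, condition, sf) {
  calc <- function(b, r) {
    vapply(c("mock", "ire1"), function(cc) {
      i <- condition == cc
      sum(b[i] / sf[i]) / sum((b[i] + r[i]) / sf[i])
    }, numeric(1))
  }
  u <- calc(bin_counts, rest_counts)
  pseudo <- FALSE
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    pseudo <- TRUE
    u <- calc(bin_counts + 0.5, rest_counts + 0.5)
  }
  list(mock = u[["mock"]], ire1 = u[["ire1"]], pseudocount = pseudo)
}

#' Signed usage fold change
#'
#' The usage odds ratio `r = [u1/(1-u1)] / [u0/(1-u0)]` (IRE1-treated over
#' mock) reported in the signed convention with `|fc| >= 1`: `fc = r` when
#' `r >= 1`, otherwise `-1/r`. Negative values mean the bin's usage is lower
#' in IRE1-treated samples, so the selection threshold "FC < -2" reads as at
#' least a two-fold usage loss.
#'
#' @param usage_mock,usage_ire1 usage fractions in (0, 1).
#' @return signed fold change.
#' @export
fold_change <- function(usage_mock, usage_ire1) {
  stopifnot(usage_mock > 0, usage_mock < 1, usage_ire1 > 0, usage_ire1 < 1)
  r <- (usage_ire1 / (1 - usage_ire1)) / (usage_mock / (1 - usage_mock))
  if (r >= 1) r else -1 / r
}

#' Differential exon usage over a whole count matrix
#'
#' Runs [test_bin()] for every unambiguous bin of every multi-bin gene,
#' with median-of-ratios size factors and per-bin method-of-moments
#' dispersions (unless supplied), then applies Benjamini-Hochberg FDR
#' correction across all testable bins. Ambiguous bins and single-bin genes
#' are carried through flagged untestable.
#'
#' @param m an [exon_count_matrix()].
#' @param dispersion optional fixed dispersion alpha used for every bin;
#'   when NULL, estimated per bin by [estimate_dispersion()].
#' @return data.frame of class `"deu_result"`: `bin_id`, `gene_id`,
#'   `rank_5to3`, `ambiguous`, `testable`, `lr_stat`, `p`, `fdr`, `fc`,
#'   `usage_mock`, `usage_ire1`.
#' @export
deu_test <- function(m, dispersion = NULL) {
  stopifnot(inherits(m, "exon_count_matrix"))
  sf <- size_factors(m)
  bins <- m$bins
  res <- data.frame(
    bin_id = bins$bin_id, gene_id = bins$gene_id, rank_5to3 = bins$rank_5to3,
    ambiguous = bins$ambiguous, testable = FALSE,
    lr_stat = NA_real_, p = NA_real_, fdr = NA_real_, fc = NA_real_,
    usage_mock = NA_real_, usage_ire1 = NA_real_, stringsAsFactors = FALSE
  )
  genes <- unique(bins$gene_id[!bins$ambiguous])
  gene_idx <- lapply(genes, function(g) which(!bins$ambiguous & bins$gene_id == g))
  names(gene_idx) <- genes
  gene_idx <- gene_idx[vapply(gene_idx, length, integer(1)) >= 2]
  # experiment-wide mean raw dispersions stabilize the per-gene shrinkage target
  prior_bin <- prior_rest <- NULL
  if (is.null(dispersion) && length(gene_idx)) {
    raws <- lapply(gene_idx, function(idx) {
      gc <- m$counts[idx, , drop = FALSE]
      rest <- sweep(-gc, 2, colSums(gc), "+")
      list(bin = raw_dispersion(gc, sf, m$condition),
           rest = raw_dispersion(rest, sf, m$condition))
    })
    prior_bin <- mean(unlist(lapply(raws, `[[`, "bin")))
    prior_rest <- mean(unlist(lapply(raws, `[[`, "rest")))
  }
  for (g in names(gene_idx)) {
    idx <- gene_idx[[g]]
    gc <- m$counts[idx, , drop = FALSE]
    tot <- colSums(gc)
    rest <- sweep(-gc, 2, tot, "+")        # per-bin rest-of-gene counts
    if (is.null(dispersion)) {
      alpha_bin <- estimate_dispersion(gc, sf, m$condition, prior = prior_bin)
      alpha_rest <- estimate_dispersion(rest, sf, m$condition, prior = prior_rest)
    } else {
      alpha_bin <- alpha_rest <- rep(dispersion, length(idx))
    }
    for (k in seq_along(idx)) {
      b <- idx[k]
      r <- test_bin(gc[k, ], rest[k, ], m$condition,
                    c(alpha_bin[k], alpha_rest[k]), sf)
      res$testable[b] <- TRUE
      res$lr_stat[b] <- r$lr_stat
      res$p[b] <- r$p
      res$fc[b] <- r$fc
      res$usage_mock[b] <- r$usage_mock
      res$usage_ire1[b] <- r$usage_ire1
    }
  }
  res$fdr[res$testable] <- stats::p.adjust(res$p[res$testable], method = "BH")
  class(res) <- c("deu_result", "data.frame")
  attr(res, "size_factors") <- sf
  res
}

#' @export
print.deu_result <- function(x, ...) {
  cat(sprintf("<deu_result> %d bins (%d testable, %d ambiguous); %d bins at FDR < 0.05\n",
              nrow(x), sum(x$testable), sum(x$ambiguous),
              sum(x$fdr < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.deu_result <- function(object, fdr_max = 0.05, fc_max = -2, ...) {
  sig <- !is.na(object$fdr) & object$fdr < fdr_max & !is.na(object$fc) &
    object$fc < fc_max
  cat(sprintf("Differential exon usage: %d/%d testable bins with FDR < %g and FC < %g (%d genes)\n",
              sum(sig), sum(object$testable), fdr_max, fc_max,
              length(unique(object$gene_id[sig]))))
  invisible(object[sig, , drop = FALSE])
}

#' Select candidate RIDD target genes
#'
#' Keeps unambiguous testable bins with `fdr < fdr_max` and `fc < fc_max`
#' (both strict inequalities, so `fc = -2` exactly is excluded), ranks genes by
#' their most negative bin fold change, and appends genes from the override
#' list regardless of their fold change (flagged `override`, mirroring the
#' manual inclusion of biologically motivated genes that miss the threshold).
#' Each gene appears once.
#'
#' @param results a `"deu_result"` data.frame.
#' @param fdr_max FDR threshold (default 0.05).
#' @param fc_max fold-change threshold (default -2).
#' @param override character vector of gene ids to append regardless of fc.
#' @return data.frame with `gene_id`, `best_fc`, `min_fdr`, `n_sig_bins`,
#'   `override`, ranked by `best_fc` ascending (override genes last).
#' @export
select_candidates <- function(results, fdr_max = 0.05, fc_max = -2,
                              override = character(0)) {
  ok <- results$testable & !results$ambiguous &
    !is.na(results$fdr) & !is.na(results$fc)
  hit <- ok & results$fdr < fdr_max & results$fc < fc_max
  empty <- data.frame(gene_id = character(0), best_fc = numeric(0),
                      min_fdr = numeric(0), n_sig_bins = integer(0),
                      override = logical(0), stringsAsFactors = FALSE)
  sel <- empty
  if (any(hit)) {
    sub <- results[hit, , drop = FALSE]
    sel <- do.call(rbind, lapply(split(sub, sub$gene_id), function(d) {
      data.frame(gene_id = d$gene_id[1], best_fc = min(d$fc),
                 min_fdr = min(d$fdr), n_sig_bins = nrow(d),
                 override = FALSE, stringsAsFactors = FALSE)
    }))
    sel <- sel[order(sel$best_fc), , drop = FALSE]
  }
  extra <- setdiff(override, sel$gene_id)
  if (length(extra)) {
    sub <- results[ok & results$gene_id %in% extra, , drop = FALSE]
    app <- do.call(rbind, lapply(split(sub, sub$gene_id), function(d) {
      data.frame(gene_id = d$gene_id[1], best_fc = min(d$fc),
                 min_fdr = min(d$fdr), n_sig_bins = sum(d$fdr < fdr_max),
                 override = TRUE, stringsAsFactors = FALSE)
    }))
    if (!is.null(app)) {
      app <- app[order(app$best_fc), , drop = FALSE]
      sel <- rbind(sel, app)
    }
  }
  rownames(sel) <- NULL
  sel
}
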