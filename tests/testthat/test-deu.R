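cond33 <- rep(c("mock", "ire1"), each = 3)

test_that("size factors follow the median-of-ratios contract", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1, 1))
  # proportional columns: ratio preserved, geometric mean 1
  m2 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  sf <- unname(size_factors(m2))
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(exp(mean(log(sf))), 1)
  expect_error(size_factors(matrix(0, 3, 2)), "all-zero")
  # no all-positive bin: total-count fallback with a warning
  m3 <- matrix(c(5, 0, 0, 10), ncol = 2)
  expect_warning(sf3 <- size_factors(m3), "falling back")
  expect_equal(unname(sf3[2] / sf3[1]), 2)
})

test_that("size factors agree with DESeq2 on well-behaved data", {
  skip_if_not_installed("DESeq2")
  set.seed(20)
  cnt <- matrix(rnbinom(300, mu = 100 * rep(exp(rnorm(6, 0, 0.3)), each = 50),
                        size = 10), nrow = 50)
  ours <- unname(size_factors(cnt))
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  ref <- unname(ref / exp(mean(log(ref))))
  # DESeq2 interpolates the even-n median in log space; we use the ratio scale
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("dispersion estimation hits its degenerate and recovery cases", {
  # replicates all equal -> 0
  cnt <- matrix(rep(c(50, 80), each = 6), nrow = 2, byrow = TRUE)
  expect_equal(unname(estimate_dispersion(cnt, rep(1, 6), cond33)), c(0, 0))
  # Monte-Carlo recovery within 25% at alpha = 0.1
  set.seed(21)
  cnt2 <- matrix(rnbinom(200 * 6, mu = 200, size = 10), nrow = 200)
  a <- estimate_dispersion(cnt2, rep(1, 6), cond33)
  expect_lt(abs(mean(a) - 0.1), 0.025)
  expect_true(all(a >= 0))
})

test_that("identical conditions give a null LR statistic", {
  b <- c(30, 32, 28, 30, 32, 28)
  r <- c(300, 310, 295, 300, 310, 295)
  res <- test_bin(b, r, cond33, alpha = 0.05, sf = rep(1, 6))
  expect_lt(res$lr_stat, 1e-6)
  expect_gt(res$p, 0.999)
})

test_that("Poisson LR equals the closed-form G-test on the collapsed 2x2 table", {
  set.seed(22)
  for (i in 1:10) {
    b <- rpois(6, 40)
    r <- rpois(6, 400)
    if (i > 5) b[4:6] <- rpois(3, 10)   # include strong-signal cases
    res <- test_bin(b, r, cond33, alpha = 0, sf = rep(1, 6))
    tab <- rbind(tapply(b, cond33, sum), tapply(r, cond33, sum))
    expect_equal(res$lr_stat, g_test_2x2(tab), tolerance = 1e-6)
  }
})

test_that("a strongly depleted bin at high depth is overwhelmingly significant", {
  sim <- simulate_ridd_experiment(n_genes = 10, n_targets = 1, epsilon = 0.9,
                                  depth = 1e6, seed = 23)
  res <- deu_test(sim$counts)
  target <- sim$truth$sites$gene_id[1]
  first_bin <- sprintf("%s:E001", target)
  expect_lt(res$p[res$bin_id == first_bin], 1e-6)
  expect_lt(res$fc[res$bin_id == first_bin], -2)
})

test_that("fold change implements the signed usage odds ratio", {
  expect_equal(fold_change(0.2, 0.05), -4.75)
  expect_equal(fold_change(0.3, 0.3), 1)
  # antisymmetry: swapping conditions flips the sign, keeps the magnitude
  expect_equal(fold_change(0.05, 0.2), -fold_change(0.2, 0.05))
  expect_error(fold_change(0, 0.5))
})

test_that("all-zero and degenerate bins are handled without error", {
  res <- test_bin(rep(0, 6), c(100, 110, 90, 100, 110, 90), cond33,
                  alpha = 0.05, sf = rep(1, 6))
  expect_equal(res$p, 1)
  expect_true(is.na(res$fc))
  expect_true(res$pseudocount)
  expect_error(test_bin(1:4, 1:4, c("mock", "mock", "ire1", "ire1")[c(1, 1, 1, 3)],
                        0.05, rep(1, 4)), "2 replicates")
})

test_that("deu_test output satisfies the BH invariants", {
  sim <- simulate_ridd_experiment(n_genes = 20, n_targets = 3, depth = 1e5,
                                  seed = 24)
  res <- deu_test(sim$counts)
  ok <- res$testable
  expect_true(all(res$fdr[ok] >= res$p[ok] - 1e-12))
  expect_true(all(res$lr_stat[ok] >= 0))
  # BH fdr is a non-decreasing step function of the p-value rank
  o <- order(res$p[ok])
  expect_true(all(diff(cummax(res$fdr[ok][o])) >= -1e-12))
  expect_identical(res$fdr[ok], p.adjust(res$p[ok], method = "BH"))
  # sign of fc agrees with the usage difference
  nz <- ok & !is.na(res$fc) & abs(res$fc) > 1
  expect_true(all(sign(res$fc[nz]) == sign(res$usage_ire1[nz] - res$usage_mock[nz])))
})

test_that("permuting condition labels destroys the signal", {
  sim <- simulate_ridd_experiment(n_genes = 15, n_targets = 5, epsilon = 0.9,
                                  depth = 2e5, seed = 25)
  m <- sim$counts
  m_perm <- exon_count_matrix(m$counts[, c(1, 4, 2, 5, 3, 6)], m$bins,
                              m$condition)   # mixes conditions within labels
  res <- deu_test(m_perm)
  expect_lt(median(res$lr_stat[res$testable]), qchisq(0.95, df = 1))
})

test_that("candidate selection applies the FDR/FC thresholds and the override list", {
  mk <- function(gene, fc, fdr) {
    data.frame(bin_id = paste0(gene, ":E001"), gene_id = gene, rank_5to3 = 1L,
               ambiguous = FALSE, testable = TRUE, lr_stat = 10,
               p = fdr / 2, fdr = fdr, fc = fc, usage_mock = 0.2,
               usage_ire1 = 0.1, stringsAsFactors = FALSE)
  }
  res <- rbind(mk("ATM", -34.9, 1e-6), mk("VPS13C", -15.96, 1e-5),
               mk("IRF4", -1.59, 0.01), mk("PRDM1", -1.71, 0.01),
               mk("EDGE", -2.0, 0.001), mk("NS", -10, 0.5))
  class(res) <- c("deu_result", "data.frame")
  sel <- select_candidates(res)
  # strongest depletion ranks first; sub-threshold and boundary genes are out
  expect_equal(sel$gene_id, c("ATM", "VPS13C"))
  expect_false("IRF4" %in% sel$gene_id)
  expect_false("EDGE" %in% sel$gene_id)    # fc = -2 exactly: strict inequality
  expect_false("NS" %in% sel$gene_id)      # fails the FDR threshold
  # override appends regardless of fold change, flagged
  sel2 <- select_candidates(res, override = c("IRF4", "PRDM1"))
  expect_equal(sel2$gene_id, c("ATM", "VPS13C", "PRDM1", "IRF4"))
  expect_equal(sel2$override, c(FALSE, FALSE, TRUE, TRUE))
  # a gene enters once even if on the override list and past threshold
  sel3 <- select_candidates(res, override = "ATM")
  expect_equal(sum(sel3$gene_id == "ATM"), 1L)
  expect_false(sel3$override[sel3$gene_id == "ATM"])
  expect_equal(nrow(select_candidates(res[0, ])), 0L)
})

test_that("null simulations are calibrated at the nominal level", {
  models <- simulate_transcriptome(80, seed = 26)
  truth <- sim_truth(models, dispersion = 0.05, seed = 26)
  m <- simulate_counts(models, truth, depth = 5e5, seed = 27)
  res <- deu_test(m)
  p <- res$p[res$testable][1:500]
  fpr <- mean(p < 0.05)
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / 500)
  expect_gt(fpr, 0.05 - half)
  expect_lt(fpr, 0.05 + half)
})
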