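test_that("transcriptome simulation honors its parameters and seed", {
  one <- simulate_transcriptome(1, exons_per_gene = c(3, 3),
                                exon_len = c(100, 100), gc = 0.5, seed = 1)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]$exons), 3)
  expect_equal(nchar(one[[1]]$sequence), 300)

  a <- simulate_transcriptome(5, seed = 1)
  b <- simulate_transcriptome(5, seed = 1)
  expect_identical(a, b)

  many <- simulate_transcriptome(200, exons_per_gene = c(2, 3),
                                 exon_len = c(30, 60), seed = 2)
  expect_equal(length(unique(vapply(many, `[[`, character(1), "gene_id"))), 200)

  expect_error(simulate_transcriptome(3, exons_per_gene = c(5, 2)), "range")
  expect_error(simulate_transcriptome(3, gc = 1.2), "gc")
})

test_that("simulated GC fraction matches the requested value", {
  models <- simulate_transcriptome(30, gc = 0.62, seed = 9)
  seqs <- paste(vapply(models, `[[`, character(1), "sequence"), collapse = "")
  x <- strsplit(seqs, "")[[1]]
  gc <- mean(x %in% c("G", "C"))
  expect_lt(abs(gc - 0.62), 3 * sqrt(0.62 * 0.38 / length(x)))
})

test_that("hairpin planting substitutes a perfect stem-loop at the stated coordinate", {
  t <- simulate_transcriptome(1, exons_per_gene = c(2, 2),
                              exon_len = c(150, 150), seed = 3)[[1]]
  res <- plant_cleavage_hairpin(t, position = 150, stem_len = 6,
                                loop = "ACUGCAG")
  expect_equal(nchar(res$model$sequence), nchar(t$sequence))  # substitution
  expect_equal(res$site$position, 150)
  # planted window: stem + loop + revcomp(stem), guanine of CUG|CAG at 150
  win <- substr(res$model$sequence, 150 - 9, 150 + 9)
  expect_equal(substr(win, 7, 13), "ACUGCAG")
  stem5 <- substr(win, 1, 6)
  stem3 <- substr(win, 14, 19)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  expect_equal(paste(rev(comp[strsplit(stem5, "")[[1]]]), collapse = ""), stem3)
  # the planted window contains exactly one consensus match
  hits <- scan_consensus(win)
  expect_length(hits, 1)
  expect_error(plant_cleavage_hairpin(t, position = 500), "outside")
  expect_error(plant_cleavage_hairpin(t, 150, loop = "AAAA"), "exactly one")
})

test_that("count means collapse correctly in the degenerate cases", {
  models <- simulate_transcriptome(4, exons_per_gene = c(3, 3), seed = 4)
  # epsilon = 0: treated and mock expected counts identical
  null_truth <- sim_truth(models, dispersion = 0)
  m0 <- simulate_counts(models, null_truth, depth = 1e5, seed = 5)
  mu <- attr(m0, "means")
  lib <- attr(m0, "library_sizes")
  norm <- sweep(mu, 2, lib, "/")
  expect_equal(rowMeans(norm[, m0$condition == "ire1"]),
               rowMeans(norm[, m0$condition == "mock"]))
  # epsilon = 1, bin entirely 5' of the cut: treated mean exactly 0
  t1 <- models[[1]]
  ex_len <- t1$exons$end - t1$exons$start
  if (t1$strand == "-") ex_len <- rev(ex_len)
  pos <- ex_len[1] + 10   # inside the second exon (transcript order)
  truth1 <- sim_truth(models, sites = data.frame(gene_id = t1$gene_id,
                                                 position = pos),
                      epsilon = 1, dispersion = 0)
  m1 <- simulate_counts(models, truth1, depth = 1e5, seed = 5)
  mu1 <- attr(m1, "means")
  first_bin <- sprintf("%s:E001", t1$gene_id)
  expect_equal(unname(mu1[first_bin, m1$condition == "ire1"]), rep(0, 3))
  # conservation: bins 3' of the cut keep their mock means
  down <- sprintf("%s:E003", t1$gene_id)
  expect_equal(mu1[down, ], mu[down, ] / attr(m0, "means")[down, 1] * mu1[down, 1])
})

test_that("empirical treated/mock ratio of a 5' bin converges to 1 - epsilon", {
  models <- simulate_transcriptome(2, exons_per_gene = c(3, 3), seed = 6)
  t1 <- models[[1]]
  ex_len <- t1$exons$end - t1$exons$start
  if (t1$strand == "-") ex_len <- rev(ex_len)
  pos <- ex_len[1] + ex_len[2]   # cut at the 3' end of exon 2
  truth <- sim_truth(models, sites = data.frame(gene_id = t1$gene_id,
                                                position = pos),
                     epsilon = 0.75, dispersion = 0,
                     library_sizes = rep(1, 4))
  # 10,000 Poisson draws of the fully-5' first bin via many small simulations
  m <- simulate_counts(models, truth, n_mock = 2, n_ire1 = 2,
                       depth = 1e4, seed = 7)
  mu <- attr(m, "means")
  first_bin <- sprintf("%s:E001", t1$gene_id)
  mock_mean <- mu[first_bin, m$condition == "mock"][1]
  set.seed(8)
  draws <- rpois(10000, lambda = mu[first_bin, m$condition == "ire1"][1])
  se <- sqrt(0.25 * mock_mean / 10000)
  expect_lt(abs(mean(draws) - 0.25 * mock_mean), 3 * se)
})

test_that("simulation is deterministic and realized counts track expected means", {
  a <- simulate_ridd_experiment(n_genes = 15, n_targets = 3, depth = 5e4, seed = 11)
  b <- simulate_ridd_experiment(n_genes = 15, n_targets = 3, depth = 5e4, seed = 11)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(vapply(a$models, `[[`, character(1), "sequence"),
                   vapply(b$models, `[[`, character(1), "sequence"))
  d <- simulate_ridd_experiment(n_genes = 15, n_targets = 3, depth = 5e4, seed = 12)
  expect_false(identical(a$counts$counts, d$counts$counts))
  # counts are non-negative integers with roughly the simulated depth
  cnt <- a$counts$counts
  expect_true(all(cnt >= 0) && all(cnt == round(cnt)))
  expect_lt(abs(sum(cnt[, 1]) / sum(attr(a$counts, "means")[, 1]) - 1), 0.1)
})

test_that("missing truth for the models is a consistency error", {
  models <- simulate_transcriptome(3, seed = 1)
  other <- simulate_transcriptome(4, seed = 2)
  truth <- sim_truth(other)
  expect_error(simulate_counts(models, truth, depth = 1e4, seed = 1),
               "does not match")
  expect_error(sim_truth(models, sites = data.frame(gene_id = "nope",
                                                    position = 10)),
               "absent")
  expect_error(sim_truth(models, sites = data.frame(
    gene_id = models[[1]]$gene_id, position = transcript_length(models[[1]]))),
    "strictly inside")
})

test_that("truth JSON round-trips", {
  sim <- simulate_ridd_experiment(n_genes = 8, n_targets = 2, depth = 2e4, seed = 3)
  path <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- read_truth_json(path)
  expect_equal(back$genes, sim$truth$genes)
  expect_equal(back$sites, sim$truth$sites)
  expect_equal(back$dispersion, sim$truth$dispersion)
  unlink(path)
})

test_that("dinucleotide shuffle preserves composition but not the motif", {
  seq <- paste0(strrep("AU", 10), "GCGCGCACUGCAGGCGCGC", strrep("GA", 10))
  dinucs <- function(s) {
    x <- strsplit(s, "")[[1]]
    sort(paste0(x[-length(x)], x[-1]))
  }
  hits <- 0
  for (i in 1:20) {
    sh <- shuffle_dinucleotide(seq, seed = i)
    expect_equal(nchar(sh), nchar(seq))
    expect_equal(dinucs(sh), dinucs(seq))
    hits <- hits + (length(scan_consensus(sh)) > 0)
  }
  expect_lt(hits, 20)   # the hexamer motif is not conserved by the shuffle
})
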