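test_that("consensus scanning finds all sense-strand occurrences", {
  expect_equal(scan_consensus("AAACUGCAGAAA"), 4L)
  expect_equal(scan_consensus("CUGCAGCUGCAG"), c(1L, 7L))
  expect_equal(scan_consensus("AAAAAAAA"), integer(0))
  # overlap-tolerant: CUGCAGCAG does not contain two, CUGCUGCAG one
  expect_equal(scan_consensus("CUGCUGCAG"), 4L)
  expect_warning(hits <- scan_consensus("AAACTGCAGAAA"), "converting T to U")
  expect_equal(hits, 4L)
  expect_error(scan_consensus("ACGX"), "non-nucleotide")
})

test_that("the worked planted hairpin scores -16.5 with the expected structure", {
  seq <- paste0("AAAAA", "GCGCGC", "ACUGCAG", "GCGCGC", "AAAAA")
  hit <- scan_consensus(seq)
  expect_length(hit, 1)
  hp <- fold_hairpin(seq, hit)
  # 6 G-C pairs (6 x -3) + 3 loop bases beyond 4 (3 x +0.5) = -16.5
  expect_equal(hp$energy, -16.5)
  expect_equal(hp$structure, "((((((.......))))))")
  expect_equal(hp$stem_len, 6)
  expect_equal(hp$cleavage_after, hit + 2L)
  # reported energy is recomputable from the structure
  expect_equal(hairpin_energy(seq, hp$structure, at = hp$hairpin_start), -16.5)
})

test_that("unstructured context yields no hairpin", {
  seq <- paste0(strrep("A", 30), "CUGCAG", strrep("A", 30))
  expect_null(fold_hairpin(seq, 31))
})

test_that("the lower-energy of two candidate stems wins", {
  # weak A-U stem just inside, strong G-C stem further out: same loop closes
  # with either; enumeration must return the stronger one
  seq <- paste0("GGGGG", "AUAUA", "ACUGCAGA", "UAUAU", "CCCCC")
  hit <- scan_consensus(seq)
  hp <- fold_hairpin(seq, hit)
  orc <- oracle_fold(seq, hit)
  expect_equal(hp$energy, orc$energy)
  expect_lte(hp$energy, -2 * 5)   # at least as stable as the pure A-U stem
})

test_that("fold_hairpin equals the exhaustive enumeration oracle on random windows", {
  set.seed(33)
  n_checked <- 0
  for (i in 1:150) {
    flank1 <- paste(sample(c("A", "C", "G", "U"), sample(10:35, 1), TRUE),
                    collapse = "")
    flank2 <- paste(sample(c("A", "C", "G", "U"), sample(10:35, 1), TRUE),
                    collapse = "")
    seq <- paste0(flank1, "CUGCAG", flank2)   # window <= 80 nt
    hit <- nchar(flank1) + 1L
    hp <- fold_hairpin(seq, hit)
    orc <- oracle_fold(seq, hit)
    expect_equal(is.null(hp), is.null(orc))
    if (!is.null(hp)) {
      n_checked <- n_checked + 1
      expect_equal(hp$energy, orc$energy)
      expect_equal(hp$loop_start, orc$loop_start)
      expect_equal(hp$stem_len, orc$stem_len)
      # structural re-validation: balanced, complementary, energy reproducible
      expect_equal(hairpin_energy(seq, hp$structure, at = hp$hairpin_start),
                   hp$energy, tolerance = 1e-9)
      expect_true(hp$loop_start <= hp$cleavage_after &&
                    hp$cleavage_after <= hp$loop_end)
    }
  }
  expect_gt(n_checked, 10)   # the random set must actually exercise folding
})

test_that("planted hairpins are always detected, shuffled windows rarely", {
  set.seed(34)
  detected <- 0
  background <- 0
  n <- 30
  for (i in 1:n) {
    ctx <- paste(sample(c("A", "C", "G", "U"), 61, TRUE), collapse = "")
    t <- transcript_model("g", "g.t", "c", "+",
                          data.frame(start = 0, end = 61), ctx)
    planted <- plant_cleavage_hairpin(t, position = 31)$model$sequence
    hit <- scan_consensus(planted)
    hp <- if (length(hit)) fold_hairpin(planted, hit[1]) else NULL
    detected <- detected + (!is.null(hp) && hp$cleavage_after == 31)
    sh <- shuffle_dinucleotide(planted, seed = i)
    sh_hit <- scan_consensus(sh)
    sh_hp <- Filter(Negate(is.null), lapply(sh_hit, function(h) fold_hairpin(sh, h)))
    background <- background + (length(sh_hp) > 0)
  }
  expect_equal(detected, n)          # detection probability 1 on planted sites
  expect_lt(background / n, 0.2)     # motif-in-hairpin background is rare
})

test_that("call_sites reports matches with window membership and energy order", {
  ctx <- strrep("A", 30)
  hairpin <- paste0("GCGCGC", "ACUGCAG", "GCGCGC")
  seq <- paste0(ctx, hairpin, ctx, hairpin, ctx)
  # consensus guanines: ctx + stem + "A.CU|G|CAG" puts them at 40 and 89
  w <- data.frame(gene_id = "g", transcript_id = "t", start = 20, end = 60)
  calls <- call_sites(w, c(t = seq))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cleavage_after, 40)
  expect_true(calls$in_window)
  # permissive scan also reports the out-of-window match, flagged
  calls2 <- call_sites(w, c(t = seq), permissive = TRUE)
  expect_equal(nrow(calls2), 2)
  expect_equal(sort(calls2$cleavage_after), c(40, 89))
  expect_equal(calls2$in_window[match(89, calls2$cleavage_after)], FALSE)
  expect_true(!is.unsorted(calls2$energy))
  # window without consensus: no call
  w0 <- data.frame(gene_id = "g", transcript_id = "t", start = 1, end = 25)
  expect_equal(nrow(call_sites(w0, c(t = seq))), 0)
  # missing sequence: skipped with a warning
  expect_warning(none <- call_sites(w, c(other = seq)), "no sequence")
  expect_equal(nrow(none), 0)
})

test_that("nearby calls group as multi-site targets", {
  calls <- data.frame(
    gene_id = "g", transcript_id = "t",
    consensus_start = c(398, 458, 898), cleavage_after = c(400, 460, 900),
    energy = c(-10, -12, -9), structure = "((((....))))",
    hairpin_start = 1, hairpin_end = 12, loop_start = 5, loop_end = 8,
    in_window = TRUE, stringsAsFactors = FALSE)
  class(calls) <- c("cleavage_calls", "data.frame")
  g <- pair_sites(calls, max_gap = 200)
  expect_equal(as.integer(table(g$group_id)[unique(g$group_id)]), c(2L, 1L))
  expect_equal(g$group_id[1], g$group_id[2])
  expect_false(g$group_id[2] == g$group_id[3])
  # empty input passes through
  expect_equal(nrow(pair_sites(calls[0, ])), 0)
})
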