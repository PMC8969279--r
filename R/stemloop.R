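IRE1_CONSENSUS <- "CUGCAG"

# pair scores of the additive hairpin energy model (arbitrary units, lower =
# more stable): G-C -3, A-U -2, G.U wobble -1; non-pairs score NA.
PAIR_SCORE <- c("GC" = -3, "CG" = -3, "AU" = -2, "UA" = -2, "GU" = -1, "UG" = -1)

pair_score <- function(b1, b2) {
  s <- PAIR_SCORE[paste0(b1, b2)]
  ifelse(is.na(s), NA_real_, s)
}

loop_penalty <- function(l) 0.5 * max(0, l - 4)

#' Scan a sequence for the IRE1 consensus CUGCAG
#'
#' All exact sense-strand occurrences; overlapping matches allowed. T is
#' converted to U with a warning.
#'
#' @param seq RNA string.
#' @return integer vector of 1-based match start positions (the C).
#' @export
scan_consensus <- function(seq) {
  if (grepl("T", toupper(seq), fixed = TRUE)) {
    warning("DNA alphabet input: converting T to U")
  }
  x <- paste(rna_chars(seq), collapse = "")
  m <- gregexpr(paste0("(?=", IRE1_CONSENSUS, ")"), x, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Fold the best hairpin presenting a consensus guanine in its loop
#'
#' Exhaustively enumerates hairpins around a CUGCAG match: an unpaired loop of
#' length `loop_range[1]..loop_range[2]` that contains the guanine at
#' consensus position 3 (the base 3' of which IRE1 cleaves), flanked by a stem
#' of at least `min_stem` consecutive complementary pairs (Watson-Crick plus
#' G.U wobble). The energy is the sum of pair scores (G-C -3, A-U -2, G.U -1)
#' plus a loop penalty of +0.5 per loop base beyond 4. The minimum-energy
#' hairpin is returned (ties broken toward the 5'-most, then shortest loop);
#' since every pair score is negative, the optimal stem for a given loop is
#' the maximal outward extension.
#'
#' @param seq RNA string (full transcript or window sequence).
#' @param match_pos 1-based position of the consensus C in `seq`.
#' @param window folding context: nucleotides considered on each side of the
#'   match (default 30).
#' @param min_stem minimum stem length in pairs (default 4).
#' @param loop_range allowed loop lengths, `c(min, max)` (default 4..12).
#' @return NULL when no hairpin satisfies the constraints, otherwise a list:
#'   `energy`, `structure` (dot-bracket over `[hairpin_start, hairpin_end]`),
#'   `hairpin_start`, `hairpin_end`, `loop_start`, `loop_end`, `stem_len`,
#'   `cleavage_after` (coordinate of the consensus guanine).
#' @export
fold_hairpin <- function(seq, match_pos, window = 30, min_stem = 4,
                         loop_range = c(4, 12)) {
  x <- rna_chars(seq)
  n <- length(x)
  if (match_pos < 1 || match_pos + 5 > n ||
      paste(x[match_pos:(match_pos + 5)], collapse = "") != IRE1_CONSENSUS) {
    stop("no CUGCAG at position ", match_pos)
  }
  g_pos <- match_pos + 2L
  lo <- max(1L, match_pos - as.integer(window))
  hi <- min(n, match_pos + 5L + as.integer(window))
  best <- NULL
  a_min <- max(lo + min_stem, g_pos - loop_range[2] + 1L)
  if (a_min > g_pos) return(NULL)
  for (a in seq(a_min, g_pos)) {
    for (l in seq(loop_range[1], loop_range[2])) {
      if (a + l - 1L < g_pos) next                  # loop must contain the guanine
      if (a + l - 1L + min_stem > hi) break
      # extend the stem outward from (a-1, a+l) as far as pairing allows
      s <- 0L
      while (a - 1L - s >= lo && a + l + s <= hi &&
             !is.na(pair_score(x[a - 1L - s], x[a + l + s]))) {
        s <- s + 1L
      }
      if (s < min_stem) next
      e <- sum(pair_score(x[(a - s):(a - 1L)], x[(a + l + s - 1L):(a + l)])) +
        loop_penalty(l)
      if (is.null(best) || e < best$energy - 1e-12) {
        best <- list(energy = e, stem_len = s, loop_start = a, loop_len = l)
      }
    }
  }
  if (is.null(best)) return(NULL)
  s <- best$stem_len
  a <- best$loop_start
  l <- best$loop_len
  list(
    energy = best$energy,
    structure = paste0(strrep("(", s), strrep(".", l), strrep(")", s)),
    hairpin_start = a - s, hairpin_end = a + l + s - 1L,
    loop_start = a, loop_end = a + l - 1L, stem_len = s,
    cleavage_after = g_pos
  )
}

#' Recompute a hairpin's energy from its dot-bracket structure
#'
#' Validates that the brackets are balanced and every paired position is
#' complementary (Watson-Crick or G.U), then returns the additive energy
#' (pair scores + loop penalty). Used to re-validate reported calls.
#'
#' @param seq RNA string covering the structure.
#' @param structure dot-bracket string of the same length as the region,
#'   starting at `at` within `seq`.
#' @param at 1-based offset of the structure in `seq` (default 1).
#' @return energy value.
#' @export
hairpin_energy <- function(seq, structure, at = 1L) {
  x <- rna_chars(seq)
  ch <- strsplit(structure, "")[[1]]
  open <- integer(0)
  pairs <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0) stop("unbalanced dot-bracket structure")
      j <- open[length(open)]
      open <- open[-length(open)]
      pairs <- rbind(pairs, c(j, i))
    }
  }
  if (length(open)) stop("unbalanced dot-bracket structure")
  if (is.null(pairs)) stop("structure contains no pairs")
  pos <- at - 1L + seq_along(ch)
  sc <- pair_score(x[pos[pairs[, 1]]], x[pos[pairs[, 2]]])
  if (anyNA(sc)) stop("non-complementary bases paired in structure")
  inner <- pairs[which.max(pairs[, 1]), ]           # innermost pair
  sum(sc) + loop_penalty(inner[2] - inner[1] - 1L)
}

#' Call cleavage sites in change-point windows
#'
#' For each window, scans for the CUGCAG consensus and folds the best hairpin
#' around every match (with folding context drawn from the full transcript
#' sequence). A call is emitted per match with a valid hairpin;
#' `cleavage_after` is the transcript coordinate of the guanine at consensus
#' position 3 (CUG|CAG). Calls are sorted by energy, most stable first. With
#' `permissive = TRUE` the whole transcript is scanned and matches outside the
#' window are reported with `in_window = FALSE`.
#'
#' @param windows data.frame from [cleavage_window()] (`gene_id`,
#'   `transcript_id`, `start`, `end`).
#' @param sequences named character vector/list of transcript RNA sequences.
#' @param window,min_stem,loop_range folding parameters, see [fold_hairpin()].
#' @param permissive scan outside the windows too (default FALSE).
#' @return data.frame of class `"cleavage_calls"`: `gene_id`, `transcript_id`,
#'   `consensus_start`, `cleavage_after`, `energy`, `structure`,
#'   `hairpin_start`, `hairpin_end`, `loop_start`, `loop_end`, `in_window`.
#' @export
call_sites <- function(windows, sequences, window = 30, min_stem = 4,
                       loop_range = c(4, 12), permissive = FALSE) {
  rows <- NULL
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    seq <- if (w$transcript_id %in% names(sequences)) {
      sequences[[w$transcript_id]]
    } else {
      NULL
    }
    if (is.null(seq) || !nzchar(seq)) {
      warning("no sequence for transcript ", w$transcript_id, "; skipping")
      next
    }
    matches <- scan_consensus(seq)
    g_pos <- matches + 2L
    in_win <- g_pos >= w$start & g_pos <= w$end
    keep <- if (permissive) seq_along(matches) else which(in_win)
    for (k in keep) {
      hp <- fold_hairpin(seq, matches[k], window = window,
                         min_stem = min_stem, loop_range = loop_range)
      if (is.null(hp)) next
      rows <- rbind(rows, data.frame(
        gene_id = w$gene_id, transcript_id = w$transcript_id,
        consensus_start = matches[k], cleavage_after = hp$cleavage_after,
        energy = hp$energy, structure = hp$structure,
        hairpin_start = hp$hairpin_start, hairpin_end = hp$hairpin_end,
        loop_start = hp$loop_start, loop_end = hp$loop_end,
        in_window = in_win[k], stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(gene_id = character(0), transcript_id = character(0),
                       consensus_start = integer(0), cleavage_after = integer(0),
                       energy = numeric(0), structure = character(0),
                       hairpin_start = integer(0), hairpin_end = integer(0),
                       loop_start = integer(0), loop_end = integer(0),
                       in_window = logical(0), stringsAsFactors = FALSE)
  }
  rows <- rows[order(rows$energy), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("cleavage_calls", "data.frame")
  rows
}

#' Group nearby cleavage-site calls
#'
#' Calls on the same transcript whose cleavage positions lie within `max_gap`
#' nucleotides of the previous call are grouped as one multi-site target
#' (several RIDD substrates carry two cleavage sites close together); isolated
#' calls pass through as singleton groups.
#'
#' @param calls a `"cleavage_calls"` data.frame.
#' @param max_gap maximum nt gap within a group (default 200).
#' @return `calls` with a `group_id` column (`<transcript>#<n>`), sorted by
#'   transcript and coordinate.
#' @export
pair_sites <- function(calls, max_gap = 200) {
  if (nrow(calls) == 0) {
    calls$group_id <- character(0)
    return(calls)
  }
  calls <- calls[order(calls$transcript_id, calls$cleavage_after), , drop = FALSE]
  gid <- character(nrow(calls))
  grp <- 0L
  prev_t <- ""
  prev_pos <- -Inf
  for (i in seq_len(nrow(calls))) {
    if (calls$transcript_id[i] != prev_t ||
        calls$cleavage_after[i] - prev_pos > max_gap) {
      grp <- grp + 1L
    }
    gid[i] <- sprintf("%s#%d", calls$transcript_id[i], grp)
    prev_t <- calls$transcript_id[i]
    prev_pos <- calls$cleavage_after[i]
  }
  calls$group_id <- gid
  rownames(calls) <- NULL
  calls
}

#' Write cleavage-site calls and their structures
#'
#' `write_calls_tsv` writes the tabular calls; `write_dotbracket` writes a
#' companion text file with, per call, a header line
#' (`transcript_id hairpin_start hairpin_end energy`), the hairpin sequence,
#' and its dot-bracket structure.
#'
#' @param calls a `"cleavage_calls"` data.frame.
#' @param path output file.
#' @param sequences named transcript sequences (for `write_dotbracket`).
#' @export
write_calls_tsv <- function(calls, path) {
  write_atomic(function(p) {
    utils::write.table(as.data.frame(calls), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

#' @rdname write_calls_tsv
#' @export
write_dotbracket <- function(calls, sequences, path) {
  write_atomic(function(p) {
    con <- file(p, "w")
    on.exit(close(con), add = TRUE)
    for (i in seq_len(nrow(calls))) {
      seq <- sequences[[calls$transcript_id[i]]]
      writeLines(c(
        sprintf(">%s %d-%d energy=%g", calls$transcript_id[i],
                calls$hairpin_start[i], calls$hairpin_end[i], calls$energy[i]),
        substr(seq, calls$hairpin_start[i], calls$hairpin_end[i]),
        calls$structure[i]
      ), con)
    }
  }, path)
}
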