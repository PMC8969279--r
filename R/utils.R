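# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit so simulations never perturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

RNA_BASES <- c("A", "C", "G", "U")

#' Reverse-complement an RNA string
#'
#' @param seq character scalar over the alphabet A/C/G/U (T tolerated, kept as U).
#' @return the reverse complement, RNA alphabet.
#' @keywords internal
rna_revcomp <- function(seq) {
  x <- rna_chars(seq)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(unname(comp[x])), collapse = "")
}

# Split an RNA string into a character vector, converting T -> U.
rna_chars <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  x[x == "T"] <- "U"
  bad <- setdiff(unique(x), RNA_BASES)
  if (length(bad) > 0) {
    stop("non-nucleotide characters in sequence: ", paste(bad, collapse = ", "))
  }
  x
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-walk shuffle (Altschul-Erickson style): the returned sequence
#' has exactly the dinucleotide composition of the input, destroying longer-range
#' motifs such as the CUGCAG consensus or a planted stem. Used to estimate the
#' background rate of stem-loop calls in cleavage windows.
#'
#' @param seq RNA string.
#' @param seed optional integer seed for reproducibility.
#' @return shuffled RNA string of the same length and dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(seq, seed = NULL) {
  with_seed(seed, {
    x <- rna_chars(seq)
    n <- length(x)
    if (n <= 2L) {
      return(paste(x, collapse = ""))
    }
    # Multigraph on observed bases; edges are the observed dinucleotides.
    edges <- split(x[-1], factor(x[-n], levels = RNA_BASES))
    last <- x[n]
    # Permute each adjacency list; accept when the final edge of every non-last
    # vertex leads (by following final edges) to the last vertex -- the
    # Eulerian-path feasibility condition, sampled by rejection.
    repeat {
      pool <- lapply(edges, function(e) e[sample.int(length(e))])
      last_edge <- vapply(RNA_BASES, function(v) {
        e <- pool[[v]]
        if (length(e) == 0L || v == last) NA_character_ else e[length(e)]
      }, character(1))
      if (edges_form_tree(last_edge, last)) break
    }
    out <- character(n)
    out[1] <- x[1]
    cur <- x[1]
    take <- stats::setNames(rep(1L, 4L), RNA_BASES)
    for (i in 2:n) {
      nxt <- pool[[cur]][take[[cur]]]
      take[[cur]] <- take[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

# Do the chosen last edges (vertex -> last_edge[vertex]) form a forest whose
# every path leads to `root`?  Standard Eulerian-path feasibility check.
edges_form_tree <- function(last_edge, root) {
  for (v in names(last_edge)) {
    if (is.na(last_edge[[v]])) next
    seen <- character(0)
    cur <- v
    while (!is.na(last_edge[[cur]])) {
      if (cur %in% seen) return(FALSE)
      seen <- c(seen, cur)
      cur <- last_edge[[cur]]
      if (cur == root) break
    }
    if (cur != root) return(FALSE)
  }
  TRUE
}

# Atomic write: write to a temp file in the same directory, then rename.
write_atomic <- function(write_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))
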