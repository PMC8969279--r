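#' Run the full RIDD discovery analysis in memory
#'
#' Chains the analysis stages on a count matrix and its gene models:
#' differential exon usage ([deu_test()]), candidate selection
#' ([select_candidates()]), depletion profiling and change-point localization
#' ([build_profile()], [localize_changepoint()], [classify_xbp1_like()]),
#' cleavage-window extraction ([cleavage_window()]) and stem-loop site calling
#' ([call_sites()], [pair_sites()]).
#'
#' @param m an [exon_count_matrix()].
#' @param models list of [transcript_model()] objects with sequences.
#' @param fdr_max,fc_max candidate thresholds (defaults 0.05 and -2).
#' @param override gene ids appended to the candidate list regardless of fc.
#' @param min_delta,min_5p_sig_fraction,max_3p_depletion XBP1-likeness
#'   thresholds, see [classify_xbp1_like()].
#' @param pad change-point window half-width in nt.
#' @param fold_window,min_stem,loop_range folding parameters, see
#'   [fold_hairpin()].
#' @param max_gap grouping distance for multi-site targets.
#' @param dispersion optional fixed NB dispersion (estimated when NULL).
#' @return object of class `"ridd_discovery"`: `deu`, `candidates`,
#'   `profiles` (list keyed by gene), `windows`, `calls`, `tallies`.
#' @export
discover_targets <- function(m, models, fdr_max = 0.05, fc_max = -2,
                             override = character(0), min_delta = 1.0,
                             min_5p_sig_fraction = 0.5, max_3p_depletion = 0.5,
                             pad = 100, fold_window = 30, min_stem = 4,
                             loop_range = c(4, 12), max_gap = 200,
                             dispersion = NULL) {
  model_by_gene <- stats::setNames(models, vapply(models, `[[`, character(1), "gene_id"))
  deu <- deu_test(m, dispersion = dispersion)
  cand <- select_candidates(deu, fdr_max = fdr_max, fc_max = fc_max,
                            override = override)
  profiles <- list()
  windows <- NULL
  deltas <- numeric(0)
  for (g in cand$gene_id) {
    pr <- build_profile(deu[!is.na(deu$gene_id) & deu$gene_id == g, ],
                        fdr_max = fdr_max)
    if (length(pr$value) < 2) next
    pr <- localize_changepoint(pr)
    pr <- classify_xbp1_like(pr, min_delta = min_delta,
                             min_5p_sig_fraction = min_5p_sig_fraction,
                             max_3p_depletion = max_3p_depletion)
    profiles[[g]] <- pr
    if (pr$xbp1_like) {
      w <- cleavage_window(pr, m$bins, model_by_gene[[g]], pad = pad)
      windows <- rbind(windows, w)
      deltas <- c(deltas, pr$depth_delta)
    }
  }
  sequences <- stats::setNames(lapply(models, `[[`, "sequence"),
                               vapply(models, `[[`, character(1), "transcript_id"))
  calls <- if (!is.null(windows)) {
    pair_sites(call_sites(windows, sequences, window = fold_window,
                          min_stem = min_stem, loop_range = loop_range),
               max_gap = max_gap)
  } else {
    pair_sites(call_sites(data.frame(gene_id = character(0),
                                     transcript_id = character(0),
                                     start = integer(0), end = integer(0)),
                          sequences))
  }
  xbp1_like <- names(profiles)[vapply(profiles, `[[`, logical(1), "xbp1_like")]
  structure(
    list(deu = deu, candidates = cand, profiles = profiles,
         windows = windows, window_deltas = deltas, calls = calls,
         tallies = list(
           bins_tested = sum(deu$testable),
           candidates = nrow(cand),
           xbp1_like = length(xbp1_like),
           calls = nrow(calls),
           genes_with_call = length(unique(calls$gene_id)),
           candidates_without_stemloop =
             length(setdiff(xbp1_like, unique(calls$gene_id))))),
    class = "ridd_discovery"
  )
}

#' @export
print.ridd_discovery <- function(x, ...) {
  t <- x$tallies
  cat("<ridd_discovery>\n")
  cat(sprintf("  bins tested:        %d\n", t$bins_tested))
  cat(sprintf("  candidate genes:    %d\n", t$candidates))
  cat(sprintf("  XBP1-like profiles: %d\n", t$xbp1_like))
  cat(sprintf("  stem-loop calls:    %d (in %d genes; %d candidates without a stem-loop)\n",
              t$calls, t$genes_with_call, t$candidates_without_stemloop))
  invisible(x)
}

#' Read a plain-text pipeline configuration
#'
#' `key = value` lines; `#` starts a comment. Values that parse as numbers
#' become numeric; comma-separated values become vectors.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else parts
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the discovery pipeline with file I/O
#'
#' Either simulates inputs (when `config$simulate` is TRUE) or reads them
#' (`config$gtf`, `config$fasta`, `config$counts`), runs
#' [discover_targets()], and writes all stage outputs plus a run-metadata
#' JSON into `config$outdir`. Outputs are written atomically and the run is
#' bit-reproducible for a fixed config and seed.
#'
#' @param config a named list or the path of a key = value file
#'   ([read_pipeline_config()]). Recognized keys: `outdir` (required), `seed`,
#'   `simulate`, simulation sizes (`n_genes`, `n_targets`, `epsilon`, `depth`,
#'   `dispersion`, `n_mock`, `n_ire1`), input paths (`gtf`, `fasta`,
#'   `counts`), thresholds (`fdr_max`, `fc_max`, `min_delta`, `min_stem`,
#'   `loop_range`, `pad`, `fold_window`, `max_gap`) and `override`.
#' @return the `"ridd_discovery"` bundle, invisibly.
#' @export
run_discovery <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  get_cfg <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  outdir <- config$outdir
  if (is.null(outdir)) stop("[config] outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(get_cfg("seed", 1))

  if (isTRUE(as.logical(get_cfg("simulate", FALSE)))) {
    sim <- stage("simulate", simulate_ridd_experiment(
      n_genes = get_cfg("n_genes", 200), n_targets = get_cfg("n_targets", 20),
      epsilon = get_cfg("epsilon", 0.85), dispersion = get_cfg("dispersion", 0.05),
      n_mock = get_cfg("n_mock", 3), n_ire1 = get_cfg("n_ire1", 3),
      depth = get_cfg("depth", 1e6), seed = seed))
    models <- sim$models
    m <- sim$counts
    stage("simulate", {
      write_transcripts_fasta(models, file.path(outdir, "transcripts.fa"))
      write_gene_models_gtf(models, file.path(outdir, "models.gtf"))
      write_counts_tsv(m, file.path(outdir, "counts.tsv"))
      write_truth_json(sim$truth, file.path(outdir, "truth.json"))
    })
  } else {
    models <- stage("annotation", {
      if (is.null(config$gtf)) stop("gtf path missing")
      if (!file.exists(config$gtf)) stop("gtf path does not exist: ", config$gtf)
      read_gene_models(config$gtf, transcript_fasta = config$fasta)
    })
    m <- stage("counts", {
      if (is.null(config$counts)) stop("counts path missing")
      read_counts_tsv(config$counts, bins = flatten_gene_models(models))
    })
  }
  stage("flatten", write_bins_tsv(m$bins, file.path(outdir, "bins.tsv")))

  res <- stage("discover", discover_targets(
    m, models,
    fdr_max = get_cfg("fdr_max", 0.05), fc_max = get_cfg("fc_max", -2),
    override = as.character(get_cfg("override", character(0))),
    min_delta = get_cfg("min_delta", 1.0),
    min_5p_sig_fraction = get_cfg("min_5p_sig_fraction", 0.5),
    max_3p_depletion = get_cfg("max_3p_depletion", 0.5),
    pad = get_cfg("pad", 100), fold_window = get_cfg("fold_window", 30),
    min_stem = get_cfg("min_stem", 4),
    loop_range = get_cfg("loop_range", c(4, 12)),
    max_gap = get_cfg("max_gap", 200)))

  stage("report", {
    write_deu_tsv(res$deu, file.path(outdir, "deu_results.tsv"))
    write_atomic(function(p) {
      utils::write.table(res$candidates, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }, file.path(outdir, "candidates.tsv"))
    write_profiles_tsv(res$profiles, file.path(outdir, "profiles.tsv"))
    if (!is.null(res$windows)) {
      write_windows_bed(res$windows, res$window_deltas,
                        file.path(outdir, "windows.bed"))
    }
    write_calls_tsv(res$calls, file.path(outdir, "calls.tsv"))
    sequences <- lapply(models, `[[`, "sequence")
    names(sequences) <- vapply(models, `[[`, character(1), "transcript_id")
    write_dotbracket(res$calls, sequences, file.path(outdir, "structures.txt"))
    meta <- list(
      package = "riddseq",
      version = as.character(utils::packageVersion("riddseq")),
      seed = seed,
      config = config[setdiff(names(config), "outdir")],
      tallies = res$tallies
    )
    write_atomic(function(p) {
      jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }, file.path(outdir, "run_metadata.json"))
  })
  invisible(res)
}

write_deu_tsv <- function(deu, path) {
  write_atomic(function(p) {
    utils::write.table(as.data.frame(deu), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

write_profiles_tsv <- function(profiles, path) {
  rows <- NULL
  for (pr in profiles) {
    rows <- rbind(rows, data.frame(
      gene_id = pr$gene_id, rank = pr$rank, bin_id = pr$bin_id,
      log2_usage_fc = pr$value, significant = pr$sig,
      changepoint = pr$changepoint, depth_delta = pr$depth_delta,
      xbp1_like = pr$xbp1_like, stringsAsFactors = FALSE))
  }
  if (is.null(rows)) {
    rows <- data.frame(gene_id = character(0), rank = integer(0),
                       bin_id = character(0), log2_usage_fc = numeric(0),
                       significant = logical(0), changepoint = integer(0),
                       depth_delta = numeric(0), xbp1_like = logical(0))
  }
  write_atomic(function(p) {
    utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Run the validation statistics on tabular inputs
#'
#' Reads whichever validation inputs the config names and writes the
#' corresponding result tables to `config$outdir`:
#' * `qpcr`: TSV with columns `gene`, `inducer`, `condition` (one of
#'   `control`, `inducer`, `inducer_4u8c`), `ct_target`, `ct_reference`
#'   (replicate rows) -> `decay_calls.tsv` via [decay_call()];
#' * `densitometry`: TSV with `protein`, `time_h`, `level` ->
#'   `half_life.tsv` via [half_life()];
#' * `viability`: TSV with `drug`, `dose`, `fa` -> `median_effect.tsv` via
#'   [fit_median_effect()];
#' * `combos`: TSV with `drug1`, `drug2`, `d1`, `d2`, `fa` -> `ci.tsv` via
#'   [combination_index()] (requires `viability`).
#'
#' @param config named list or key = value file path; `outdir` required,
#'   optional `alpha`, `rescue_fraction`.
#' @return named list of the result data.frames, invisibly.
#' @export
run_validation <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- config$outdir
  if (is.null(outdir)) stop("[config] outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  alpha <- if (!is.null(config$alpha)) config$alpha else 0.05
  rescue_fraction <- if (!is.null(config$rescue_fraction)) config$rescue_fraction else 0.75
  out <- list()

  if (!is.null(config$qpcr)) {
    qp <- stage("qpcr", {
      df <- utils::read.delim(config$qpcr, stringsAsFactors = FALSE)
      need <- c("gene", "inducer", "condition", "ct_target", "ct_reference")
      if (!all(need %in% names(df))) stop("qpcr table needs columns: ",
                                          paste(need, collapse = ", "))
      df
    })
    rows <- NULL
    if (nrow(qp) == 0) {
      warning("empty qPCR table; writing empty decay-call output")
    }
    for (key in unique(paste(qp$gene, qp$inducer, sep = "\r"))) {
      if (nrow(qp) == 0) break
      gi <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- qp[qp$gene == gi[1] & qp$inducer == gi[2], ]
      pick <- function(cond) {
        s <- sub[sub$condition == cond, ]
        if (nrow(s) == 0) stop(sprintf("gene %s / inducer %s lacks condition '%s'",
                                       gi[1], gi[2], cond))
        list(target_ct = s$ct_target, reference_ct = s$ct_reference)
      }
      dc <- stage("qpcr", decay_call(pick("control"), pick("inducer"),
                                     pick("inducer_4u8c"), alpha = alpha,
                                     rescue_fraction = rescue_fraction))
      rows <- rbind(rows, data.frame(
        gene = gi[1], inducer = gi[2],
        expr_control = dc$expr_control, expr_treated = dc$expr_treated,
        expr_treated_plus_4u8c = dc$expr_treated_plus_4u8c,
        p_decay = dc$p_decay, p_rescue = dc$p_rescue,
        ire1_dependent = dc$ire1_dependent, stringsAsFactors = FALSE))
    }
    if (is.null(rows)) {
      rows <- data.frame(gene = character(0), inducer = character(0),
                         expr_control = numeric(0), expr_treated = numeric(0),
                         expr_treated_plus_4u8c = numeric(0),
                         p_decay = numeric(0), p_rescue = numeric(0),
                         ire1_dependent = logical(0))
    }
    out$decay_calls <- rows
    write_atomic(function(p) {
      utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(outdir, "decay_calls.tsv"))
  }

  if (!is.null(config$densitometry)) {
    dn <- stage("half_life", utils::read.delim(config$densitometry,
                                               stringsAsFactors = FALSE))
    rows <- do.call(rbind, lapply(split(dn, dn$protein), function(d) {
      hl <- stage("half_life", half_life(d$time_h, d$level))
      data.frame(protein = d$protein[1], t_half_h = hl$t_half, k_per_h = hl$k,
                 r2 = hl$r2, stringsAsFactors = FALSE)
    }))
    out$half_life <- rows
    write_atomic(function(p) {
      utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(outdir, "half_life.tsv"))
  }

  fits <- NULL
  if (!is.null(config$viability)) {
    vb <- stage("median_effect", utils::read.delim(config$viability,
                                                   stringsAsFactors = FALSE))
    fits <- lapply(split(vb, vb$drug), function(d) {
      stage("median_effect", fit_median_effect(d$dose, fa = d$fa))
    })
    rows <- do.call(rbind, lapply(names(fits), function(dr) {
      f <- fits[[dr]]
      data.frame(drug = dr, m = f$m, Dm = f$Dm, r2 = f$r2, n = f$n,
                 stringsAsFactors = FALSE)
    }))
    out$median_effect <- rows
    write_atomic(function(p) {
      utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(outdir, "median_effect.tsv"))
  }

  if (!is.null(config$combos)) {
    if (is.null(fits)) stop("[ci] combos require a viability table for single-drug fits")
    cb <- stage("ci", utils::read.delim(config$combos, stringsAsFactors = FALSE))
    cb$ci <- vapply(seq_len(nrow(cb)), function(i) {
      stage("ci", combination_index(fits[[cb$drug1[i]]], fits[[cb$drug2[i]]],
                                    cb$d1[i], cb$d2[i], cb$fa[i]))
    }, numeric(1))
    out$ci <- cb
    write_atomic(function(p) {
      utils::write.table(cb, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(outdir, "ci.tsv"))
  }
  invisible(out)
}
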