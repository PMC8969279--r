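#' Transcript model
#'
#' A minimal description of one transcript: its gene, strand, exon structure on
#' the genome, and spliced sequence. This is the unit of simulation and of
#' coordinate mapping between genome and transcript.
#'
#' Coordinate conventions, used throughout the package:
#' * genomic intervals are 0-based, half-open `[start, end)` (BED-style);
#'   GTF input/output is converted from/to 1-based inclusive at the boundary;
#' * single genomic positions are 0-based;
#' * transcript coordinates are 1-based positions along the spliced mRNA,
#'   5' to 3' (so base 1 of a minus-strand transcript is the genomically
#'   rightmost exonic base).
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end` (0-based
#'   half-open), non-overlapping; will be sorted genomically.
#' @param sequence spliced mRNA sequence, 5' to 3', RNA alphabet (T accepted
#'   and converted to U), or `NULL` when only coordinates are needed. When
#'   present, its length must equal the summed exon length.
#' @return an object of class `"transcript_model"`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons, sequence) {
  stopifnot(is.character(gene_id), is.character(transcript_id))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) stop("exon with end <= start")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in one transcript")
  }
  if (!is.null(sequence)) {
    sequence <- paste(rna_chars(sequence), collapse = "")
    if (nchar(sequence) != sum(exons$end - exons$start)) {
      stop("sequence length does not match summed exon length")
    }
  }
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons, sequence = sequence),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x)))
  invisible(x)
}

transcript_length <- function(t) sum(t$exons$end - t$exons$start)

#' Map a genomic position to a transcript coordinate
#'
#' @param t a [transcript_model()].
#' @param gpos 0-based genomic position; must fall inside an exon of `t`.
#' @return 1-based transcript coordinate.
#' @export
genomic_to_transcript <- function(t, gpos) {
  ex <- t$exons
  hit <- which(gpos >= ex$start & gpos < ex$end)
  if (length(hit) != 1L) {
    stop(sprintf("genomic position %d is not exonic in transcript %s",
                 gpos, t$transcript_id))
  }
  before <- if (hit > 1) sum(ex$end[seq_len(hit - 1)] - ex$start[seq_len(hit - 1)]) else 0L
  plus_off <- before + (gpos - ex$start[hit])   # 0-based offset on the + sense
  if (t$strand == "+") plus_off + 1L else transcript_length(t) - plus_off
}

#' Map a transcript coordinate back to the genome
#'
#' Inverse of [genomic_to_transcript()]: `transcript_to_genomic(t,
#' genomic_to_transcript(t, g)) == g` for every exonic genomic position `g`.
#'
#' @param t a [transcript_model()].
#' @param tpos 1-based transcript coordinate in `[1, length]`.
#' @return 0-based genomic position.
#' @export
transcript_to_genomic <- function(t, tpos) {
  len <- transcript_length(t)
  if (tpos < 1 || tpos > len) {
    stop(sprintf("transcript coordinate %d outside [1, %d]", tpos, len))
  }
  plus_off <- if (t$strand == "+") tpos - 1L else len - tpos
  ex <- t$exons
  widths <- ex$end - ex$start
  cum <- cumsum(widths)
  hit <- which(plus_off < cum)[1]
  before <- if (hit > 1) cum[hit - 1] else 0L
  ex$start[hit] + (plus_off - before)
}

#' Extract the spliced transcript sequence from a genome
#'
#' Concatenates the exon sequences in genomic order and reverse-complements for
#' minus-strand transcripts, returning the mRNA 5' to 3'.
#'
#' @param t a [transcript_model()].
#' @param genome named character vector of chromosome sequences (DNA or RNA
#'   alphabet; position 1 of the string is genomic position 0).
#' @return RNA string.
#' @export
spliced_sequence <- function(t, genome) {
  if (!t$chrom %in% names(genome)) stop("chromosome ", t$chrom, " not in genome")
  chrseq <- genome[[t$chrom]]
  pieces <- mapply(function(s, e) substr(chrseq, s + 1L, e),
                   t$exons$start, t$exons$end)
  plus <- paste(rna_chars(paste(pieces, collapse = "")), collapse = "")
  if (t$strand == "+") plus else rna_revcomp(plus)
}

# Genomic-sense sequence of the transcript's exons (left to right on the
# genome), derived from the stored spliced sequence. Used to embed transcripts
# in a synthetic genome and to write exon blocks.
plus_sense_sequence <- function(t) {
  if (t$strand == "+") t$sequence else rna_revcomp(t$sequence)
}
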