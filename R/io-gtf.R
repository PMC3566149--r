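#' Read transcript models from a GENCODE-dialect GTF
#'
#' Only `exon` features are used; all other feature types are ignored. GTF
#' coordinates (1-based inclusive) are converted to the package-internal
#' 0-based half-open convention on read. The transcript biotype is taken from
#' the `transcript_type` attribute, falling back to `transcript_biotype`.
#' Biotypes outside the six lncRNA biotypes and `protein_coding` are retained
#' verbatim but flagged (`biotype_known = FALSE`).
#'
#' @param path Path to a GTF2.2 file.
#' @return An exon-level data.frame (class `transcript_set`) with columns
#'   `transcript_id`, `gene_id`, `biotype`, `biotype_known`, `chrom`,
#'   `strand`, `start`, `end`, `exon_index` (0-based, in genomic-start order).
#'   One row per exon; exons within a transcript are non-overlapping, sorted
#'   by genomic start, and on a single chromosome and strand.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) return(empty_transcripts())
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("transcript_type" %in% names(mc)) {
    as.character(mc$transcript_type)
  } else if ("transcript_biotype" %in% names(mc)) {
    as.character(mc$transcript_biotype)
  } else {
    rep(NA_character_, length(gr))
  }
  df <- data.frame(
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    biotype = biotype,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  as_transcript_set(df)
}

#' Build a validated transcript set from an exon table
#'
#' @param df Exon-level data.frame with `transcript_id`, `gene_id`,
#'   `biotype`, `chrom`, `strand`, `start`, `end` (0-based half-open).
#' @return The validated, sorted `transcript_set` with `exon_index` and
#'   `biotype_known` columns added.
#' @export
as_transcript_set <- function(df) {
  if (!nrow(df)) return(empty_transcripts())
  validate_intervals(df, "exon")
  for (tid in unique(df$transcript_id)) {
    ex <- df[df$transcript_id == tid, ]
    if (length(unique(ex$chrom)) > 1L || length(unique(ex$strand)) > 1L) {
      stop_located("GTF validation error", tid,
                   "exons span multiple chromosomes or strands")
    }
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop_located("GTF validation error", tid, "exons overlap")
    }
  }
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  idx <- stats::ave(df$start, df$transcript_id, FUN = seq_along) - 1L
  df$exon_index <- as.integer(idx)
  df$biotype_known <- df$biotype %in% c(lnc_biotypes(), "protein_coding")
  rownames(df) <- NULL
  class(df) <- c("transcript_set", "data.frame")
  df
}

empty_transcripts <- function() {
  df <- data.frame(transcript_id = character(), gene_id = character(),
                   biotype = character(), chrom = character(),
                   strand = character(), start = integer(), end = integer(),
                   exon_index = integer(), biotype_known = logical(),
                   stringsAsFactors = FALSE)
  class(df) <- c("transcript_set", "data.frame")
  df
}

#' Write a transcript set as GTF
#'
#' Emits `exon` features with GENCODE-style attributes; internal 0-based
#' half-open coordinates are shifted back to GTF 1-based inclusive.
#'
#' @param transcripts A `transcript_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- sprintf(
    paste0("%s\tmrenet\texon\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; transcript_id \"%s\"; transcript_type \"%s\";"),
    transcripts$chrom, transcripts$start + 1L, transcripts$end,
    transcripts$strand, transcripts$gene_id, transcripts$transcript_id,
    transcripts$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Spliced length of each transcript
#'
#' @param transcripts A `transcript_set`.
#' @return Named integer vector of summed exon lengths per transcript.
#' @export
spliced_lengths <- function(transcripts) {
  len <- transcripts$end - transcripts$start
  out <- tapply(len, transcripts$transcript_id, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Map a biotype to its target class
#'
#' `protein_coding` transcripts are class `mRNA`; every other biotype is
#' treated as class `lncRNA` for annotation purposes.
#'
#' @param biotype Character vector of biotypes.
#' @return Character vector over `{lncRNA, mRNA}`.
#' @export
biotype_class <- function(biotype) {
  ifelse(biotype == "protein_coding", "mRNA", "lncRNA")
}
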