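#' Convert genomic positions to spliced transcript coordinates
#'
#' @param exons Exon rows of a single transcript (a `transcript_set` subset),
#'   sorted or unsorted.
#' @param gpos Integer vector of 0-based genomic positions; every position
#'   must fall inside an exon.
#' @return Integer vector of 0-based offsets from the transcript 5' end
#'   (exon lengths accumulated; reversed for minus-strand transcripts).
#' @export
genomic_to_transcript <- function(exons, gpos) {
  exons <- exons[order(exons$start), , drop = FALSE]
  lens <- exons$end - exons$start
  before <- cumsum(c(0L, lens))[seq_len(nrow(exons))]
  total <- sum(lens)
  out <- vapply(gpos, function(g) {
    i <- which(g >= exons$start & g < exons$end)
    if (!length(i)) {
      stop_located("coordinate error", exons$transcript_id[1],
                   sprintf("genomic position %d is intronic or outside the transcript", g))
    }
    as.numeric(before[i] + (g - exons$start[i]))
  }, numeric(1))
  if (exons$strand[1] == "-") out <- total - 1L - out
  as.integer(out)
}

#' Convert spliced transcript coordinates back to genomic positions
#'
#' Inverse of [genomic_to_transcript()] on every exonic base.
#'
#' @param exons Exon rows of a single transcript.
#' @param tpos Integer vector of 0-based spliced positions.
#' @return Integer vector of 0-based genomic positions.
#' @export
transcript_to_genomic <- function(exons, tpos) {
  exons <- exons[order(exons$start), , drop = FALSE]
  lens <- exons$end - exons$start
  total <- sum(lens)
  assert_that(all(tpos >= 0L & tpos < total),
              "spliced position outside transcript")
  p <- if (exons$strand[1] == "-") total - 1L - tpos else tpos
  before <- cumsum(c(0L, lens))
  i <- findInterval(p, before, rightmost.closed = FALSE)
  as.integer(exons$start[i] + (p - before[i]))
}

#' Assign recognition elements to transcript exons
#'
#' Produces one annotation per (element, transcript, overlapped exon) triple
#' with >= 1 base of genomic overlap with exonic sequence (intron-only
#' overlaps are discarded). An element overlapping several transcripts
#' annotates each of them; the transcript-coordinate span is the element's
#' overlap clipped to the exon, expressed 0-based half-open 5'->3' in
#' transcript orientation.
#'
#' @param elements Recognition elements from [call_clusters()].
#' @param transcripts A `transcript_set`.
#' @param same_strand If `TRUE` (default), elements only annotate transcripts
#'   on the same strand.
#' @return Data.frame with columns `cluster_id`, `transcript_id`, `gene_id`,
#'   `biotype`, `biotype_class`, `exon_index`, `tx_start`, `tx_end`, sorted
#'   by (cluster_id, transcript_id, exon_index).
#' @export
assign_clusters <- function(elements, transcripts, same_strand = TRUE) {
  empty <- data.frame(cluster_id = character(), transcript_id = character(),
                      gene_id = character(), biotype = character(),
                      biotype_class = character(), exon_index = integer(),
                      tx_start = integer(), tx_end = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(elements) || !nrow(transcripts)) return(empty)
  el_gr <- GenomicRanges::GRanges(
    elements$chrom,
    IRanges::IRanges(elements$start + 1L, elements$end),
    strand = elements$strand)
  ex_gr <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(transcripts$start + 1L, transcripts$end),
    strand = transcripts$strand)
  ov <- GenomicRanges::findOverlaps(el_gr, ex_gr,
                                    ignore.strand = !same_strand)
  if (!length(ov)) return(empty)
  ei <- S4Vectors::queryHits(ov)
  xi <- S4Vectors::subjectHits(ov)
  rows <- lapply(seq_along(ei), function(k) {
    el <- elements[ei[k], ]
    ex <- transcripts[xi[k], ]
    tx <- transcripts[transcripts$transcript_id == ex$transcript_id, ]
    os <- max(el$start, ex$start)
    oe <- min(el$end, ex$end)
    if (ex$strand == "+") {
      ts <- genomic_to_transcript(tx, os)
      te <- genomic_to_transcript(tx, oe - 1L) + 1L
    } else {
      ts <- genomic_to_transcript(tx, oe - 1L)
      te <- genomic_to_transcript(tx, os) + 1L
    }
    data.frame(cluster_id = el$cluster_id, transcript_id = ex$transcript_id,
               gene_id = ex$gene_id, biotype = ex$biotype,
               biotype_class = biotype_class(ex$biotype),
               exon_index = ex$exon_index, tx_start = ts, tx_end = te,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_id, out$transcript_id, out$exon_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap summary counts
#'
#' Counts distinct exons (transcript-level: distinct
#' `(transcript_id, exon_index)` pairs), transcripts, genes and clusters per
#' target class. Gene-level exon collapsing is reported alongside the
#' default transcript-level unit.
#'
#' @param annotations Output of [assign_clusters()].
#' @return Data.frame with one row per `biotype_class` and columns
#'   `n_exons`, `n_exons_gene_level`, `n_transcripts`, `n_genes`,
#'   `n_clusters`.
#' @export
count_overlaps <- function(annotations) {
  classes <- c("lncRNA", "mRNA")
  rows <- lapply(classes, function(cl) {
    a <- annotations[annotations$biotype_class == cl, , drop = FALSE]
    data.frame(
      biotype_class = cl,
      n_exons = length(unique(paste(a$transcript_id, a$exon_index))),
      n_exons_gene_level = length(unique(paste(a$gene_id, a$exon_index))),
      n_transcripts = length(unique(a$transcript_id)),
      n_genes = length(unique(a$gene_id)),
      n_clusters = length(unique(a$cluster_id)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
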