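#' Merge per-Argonaute read sets
#'
#' The four Ago PAR-CLIP libraries are pooled before cluster calling; source
#' tags are preserved so per-Ago support can be reported afterwards.
#'
#' @param read_sets Named list of mapped-read data.frames
#'   (see [read_bed()]); the list name overrides the `ago_source` column
#'   when present.
#' @return A single mapped-read data.frame.
#' @export
merge_sources <- function(read_sets) {
  if (!length(read_sets)) return(empty_reads())
  stamped <- lapply(seq_along(read_sets), function(i) {
    df <- read_sets[[i]]
    if (!is.null(names(read_sets)) && nzchar(names(read_sets)[i])) {
      if (nrow(df)) df$ago_source <- names(read_sets)[i]
    }
    df
  })
  out <- do.call(rbind, stamped)
  if (!nrow(out)) return(empty_reads())
  key <- paste(out$read_id, out$ago_source)
  if (anyDuplicated(key)) {
    stop_located("merge error", key[which(duplicated(key))[1]],
                 "duplicate (read_id, source) pair")
  }
  rownames(out) <- NULL
  out
}

#' Run-length encoded per-base coverage on one chromosome and strand
#'
#' @param reads Mapped-read data.frame, all on one chromosome and strand.
#' @return Data.frame of maximal constant-depth runs with columns `start`,
#'   `end` (0-based half-open) and `depth` (> 0 runs only). The total
#'   mapped bases sum(run length x depth) equals the summed read lengths.
#' @export
pileup <- function(reads) {
  if (!nrow(reads)) {
    return(data.frame(start = integer(), end = integer(), depth = integer()))
  }
  assert_that(length(unique(reads$chrom)) == 1L &&
                length(unique(reads$strand)) == 1L,
              "pileup expects reads on a single chromosome and strand")
  cov <- IRanges::coverage(IRanges::IRanges(reads$start + 1L, reads$end))
  rl <- S4Vectors::runLength(cov)
  rv <- S4Vectors::runValue(cov)
  ends <- cumsum(rl)            # 1-based inclusive run ends == 0-based half-open ends
  starts <- ends - rl           # 0-based starts
  keep <- rv > 0L
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]),
             depth = as.integer(rv[keep]))
}

#' Call high-confidence miRNA recognition elements
#'
#' A recognition element is a maximal contiguous run of genomic positions
#' whose merged (all-Ago) per-base read coverage is at least `min_depth`
#' (default 5, the PAR-CLIP high-confidence criterion). Calling is stranded
#' by default: reads on opposite strands never co-accumulate.
#'
#' @param reads Mapped-read data.frame (typically from [merge_sources()]).
#' @param min_depth Minimum per-base merged coverage (>= 1).
#' @param ignore_strand If `TRUE`, reads are pooled per chromosome regardless
#'   of strand and elements are reported on the plus strand.
#' @param sources Declared Ago label set; every element reports a support
#'   count (possibly 0) for each. Defaults to the labels present in `reads`.
#' @return Data.frame of elements sorted by (chrom, start, strand) with
#'   columns `chrom`, `start`, `end`, `strand`, `cluster_id`, `max_depth`,
#'   `total_support` and one `support_<source>` column per declared source
#'   (number of that source's reads overlapping the element by >= 1 base).
#' @export
call_clusters <- function(reads, min_depth = 5L, ignore_strand = FALSE,
                          sources = NULL) {
  assert_that(min_depth >= 1L, "min_depth must be >= 1")
  if (is.null(sources)) sources <- sort(unique(reads$ago_source))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      cluster_id = character(), max_depth = integer(),
                      total_support = integer(), stringsAsFactors = FALSE)
  for (s in sources) empty[[paste0("support_", s)]] <- integer()
  if (!nrow(reads)) return(empty)
  validate_intervals(reads, "read")

  if (ignore_strand) {
    reads$strand <- "+"
  }
  groups <- split(reads, paste(reads$chrom, reads$strand))
  out <- lapply(groups, function(g) {
    chrom <- g$chrom[1]
    strand <- g$strand[1]
    cov <- IRanges::coverage(IRanges::IRanges(g$start + 1L, g$end))
    runs <- IRanges::slice(cov, lower = min_depth, rangesOnly = FALSE)
    if (!length(runs)) return(NULL)
    ir <- IRanges::ranges(runs)   # 1-based inclusive
    start0 <- IRanges::start(ir) - 1L
    end0 <- IRanges::end(ir)
    max_depth <- vapply(seq_along(runs), function(i) max(runs[[i]]), integer(1))
    el <- data.frame(chrom = chrom, start = start0, end = end0,
                     strand = strand,
                     cluster_id = sprintf("%s:%d-%d:%s", chrom, start0, end0,
                                          strand),
                     max_depth = max_depth, stringsAsFactors = FALSE)
    readr <- IRanges::IRanges(g$start + 1L, g$end)
    total <- integer(nrow(el))
    for (s in sources) {
      cnt <- IRanges::countOverlaps(ir, readr[g$ago_source == s])
      el[[paste0("support_", s)]] <- as.integer(cnt)
      total <- total + as.integer(cnt)
    }
    el$total_support <- total
    el
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  cols <- c("chrom", "start", "end", "strand", "cluster_id", "max_depth",
            "total_support", paste0("support_", sources))
  out[, cols, drop = FALSE]
}

#' Per-Argonaute contribution summary
#'
#' For each Ago source, counts the lncRNA-overlapping recognition elements
#' it supports (support > 0), the distinct lncRNA transcripts those elements
#' annotate, and the union of cognate miRNAs predicted at them; also returns
#' the element x source presence matrix used for presence/absence heatmaps.
#'
#' @param elements Recognition-element data.frame from [call_clusters()].
#' @param annotations Cluster annotations from [assign_clusters()].
#' @param hits Duplex hits from [predict_targets()] (may be empty).
#' @param sources Ago label set; default inferred from `elements` columns.
#' @return List with `summary` (data.frame: `ago_source`, `n_elements`,
#'   `n_transcripts`, `mirnas` list-column) and `presence` (logical matrix,
#'   elements x sources).
#' @export
summarize_ago_contributions <- function(elements, annotations, hits,
                                        sources = NULL) {
  if (is.null(sources)) {
    sources <- sub("^support_", "",
                   grep("^support_", names(elements), value = TRUE))
  }
  presence <- matrix(FALSE, nrow(elements), length(sources),
                     dimnames = list(elements$cluster_id, sources))
  for (s in sources) {
    col <- paste0("support_", s)
    if (col %in% names(elements)) presence[, s] <- elements[[col]] > 0L
  }
  lnc_ann <- annotations[annotations$biotype_class == "lncRNA", , drop = FALSE]
  rows <- lapply(sources, function(s) {
    supported <- elements$cluster_id[presence[, s]]
    ann <- lnc_ann[lnc_ann$cluster_id %in% supported, , drop = FALSE]
    mir <- character()
    if (!is.null(hits) && nrow(hits)) {
      mir <- sort(unique(
        hits$mirna_id[hits$cluster_id %in% ann$cluster_id &
                        hits$transcript_id %in% ann$transcript_id]))
    }
    data.frame(ago_source = s,
               n_elements = length(unique(ann$cluster_id)),
               n_transcripts = length(unique(ann$transcript_id)),
               mirnas = I(list(mir)), stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), presence = presence)
}
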