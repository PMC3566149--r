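#' Relative position of an annotated element along its transcript
#'
#' Midpoint rule: the midpoint of the element's spliced-coordinate span,
#' divided by the spliced transcript length, clamped into `[0, 1)` so that a
#' midpoint at exactly the 3' end falls into the last bin.
#'
#' @param annotations Annotation data.frame (see [assign_clusters()]).
#' @param transcripts A `transcript_set` containing every annotated
#'   transcript.
#' @return Numeric vector of fractions in `[0, 1)`, one per annotation row.
#' @export
relative_position <- function(annotations, transcripts) {
  lens <- spliced_lengths(transcripts)
  missing <- setdiff(annotations$transcript_id, names(lens))
  if (length(missing)) {
    stop_located("positional profile error", missing[1],
                 "annotation references a transcript absent from the annotation set")
  }
  L <- unname(lens[annotations$transcript_id])
  frac <- ((annotations$tx_start + annotations$tx_end) / 2) / L
  pmin(pmax(frac, 0), 1 - 1e-9)
}

#' Bin recognition elements along normalized transcript length
#'
#' Divides each transcript into `n_bins` non-overlapping equal-length bins
#' (default ten 10% bins, 0 = 5'-most decile, `n_bins - 1` = 3'-most) and
#' counts annotated elements per bin by the midpoint rule. An element
#' annotating k transcripts contributes k times (per-transcript binning)
#' unless `distinct_clusters = TRUE`, which keeps one annotation per cluster
#' (the 5'-most).
#'
#' @param annotations Annotation data.frame.
#' @param transcripts A `transcript_set`.
#' @param n_bins Number of bins (>= 1).
#' @param distinct_clusters Collapse to one annotation per cluster first.
#' @param per_source Optional elements data.frame from [call_clusters()];
#'   when given, a source-stratified count matrix is included.
#' @return A `positional_profile` list: `n_bins`, `counts` (length
#'   `n_bins`), `n_assigned`, and optionally `per_source_counts`
#'   (bins x sources).
#' @export
bin_elements <- function(annotations, transcripts, n_bins = 10L,
                         distinct_clusters = FALSE, per_source = NULL) {
  assert_that(n_bins >= 1L, "n_bins must be >= 1")
  ann <- annotations
  if (distinct_clusters && nrow(ann)) {
    ann <- ann[order(ann$cluster_id, ann$tx_start), , drop = FALSE]
    ann <- ann[!duplicated(ann$cluster_id), , drop = FALSE]
  }
  if (!nrow(ann)) {
    prof <- list(n_bins = as.integer(n_bins), counts = integer(n_bins),
                 n_assigned = 0L)
    class(prof) <- "positional_profile"
    return(prof)
  }
  frac <- relative_position(ann, transcripts)
  bin <- pmin(floor(frac * n_bins), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  prof <- list(n_bins = as.integer(n_bins), counts = as.integer(counts),
               n_assigned = nrow(ann))
  if (!is.null(per_source)) {
    sources <- sub("^support_", "",
                   grep("^support_", names(per_source), value = TRUE))
    mat <- matrix(0L, n_bins, length(sources),
                  dimnames = list(NULL, sources))
    for (s in sources) {
      supported <- per_source$cluster_id[per_source[[paste0("support_", s)]] > 0L]
      sel <- ann$cluster_id %in% supported
      mat[, s] <- tabulate(bin[sel] + 1L, nbins = n_bins)
    }
    prof$per_source_counts <- mat
  }
  class(prof) <- "positional_profile"
  prof
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("positional_profile: %d annotations over %d bins\n",
              x$n_assigned, x$n_bins))
  print(stats::setNames(x$counts,
                        sprintf("[%d%%,%d%%)",
                                round(100 * (seq_len(x$n_bins) - 1) / x$n_bins),
                                round(100 * seq_len(x$n_bins) / x$n_bins))))
  invisible(x)
}

#' Write a positional profile as TSV
#'
#' @param profile A `positional_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  lo <- (seq_len(profile$n_bins) - 1) / profile$n_bins
  hi <- seq_len(profile$n_bins) / profile$n_bins
  df <- data.frame(bin_index = seq_len(profile$n_bins) - 1L,
                   bin_range = sprintf("[%.2f,%.2f)", lo, hi),
                   count = profile$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
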