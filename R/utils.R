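#' @keywords internal
"_PACKAGE"

## Internal validation helpers shared across modules.

#' lncRNA biotypes recognised by the pipeline
#'
#' The six GENCODE long-noncoding biotypes handled by the annotation stage;
#' every other non-protein-coding biotype is retained but flagged.
#'
#' @return Character vector of biotype names.
#' @export
lnc_biotypes <- function() {
  c("processed_transcript", "antisense", "lincRNA",
    "ncRNA_host", "noncoding", "retained_intron")
}

#' Known Argonaute source labels
#'
#' Default label set for the four Argonaute PAR-CLIP libraries. The label set
#' is extensible: any character label is accepted where a `sources` argument
#' is exposed.
#'
#' @return Character vector.
#' @export
ago_sources <- function() c("Ago1", "Ago2", "Ago3", "Ago4")

stop_located <- function(what, where, msg) {
  stop(sprintf("%s (%s): %s", what, where, msg), call. = FALSE)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Validate a data.frame of 0-based half-open stranded intervals.
validate_intervals <- function(df, what = "interval") {
  assert_that(all(c("chrom", "start", "end", "strand") %in% names(df)),
              sprintf("%s table must have chrom/start/end/strand columns", what))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop_located("validation error", paste0(what, " row ", bad[1]),
                 sprintf("require 0 <= start < end, got start=%s end=%s",
                         df$start[bad[1]], df$end[bad[1]]))
  }
  badstrand <- which(!df$strand %in% c("+", "-"))
  if (length(badstrand)) {
    stop_located("validation error", paste0(what, " row ", badstrand[1]),
                 sprintf("strand must be '+' or '-', got '%s'",
                         df$strand[badstrand[1]]))
  }
  invisible(df)
}

# Stable lexicographic order used for every exported table.
order_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
}

empty_reads <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), read_id = character(),
             ago_source = character(), stringsAsFactors = FALSE)
}
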