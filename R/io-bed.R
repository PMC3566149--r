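#' Read PAR-CLIP read mappings from a BED6 file
#'
#' Coordinates are BED-native 0-based half-open and are kept that way
#' internally; all coordinate conversion in the package happens only at I/O
#' boundaries. Every record is stamped with the Argonaute source label of the
#' library it came from.
#'
#' @param path Path to a BED6 file (chrom, start, end, name, score, strand).
#' @param source_label Argonaute library label stamped on every read
#'   (e.g. `"Ago1"`).
#' @param assume_plus_strand If `TRUE`, unstranded records (`"."`) are mapped
#'   to the plus strand instead of raising an error. PAR-CLIP is
#'   strand-specific, so the default is to fail loudly.
#' @return A data.frame of mapped reads with columns `chrom`, `start`, `end`,
#'   `strand`, `read_id`, `ago_source`.
#' @export
read_bed <- function(path, source_label, assume_plus_strand = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_reads())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    i <- which(nf < 6)[1]
    stop_located("BED parse error", sprintf("%s line %d", path, i),
                 sprintf("expected >= 6 tab-separated fields, got %d", nf[i]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop_located("BED parse error", sprintf("%s line %d", path, bad[1]),
                 "start/end are not integers")
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop_located("BED validation error", sprintf("%s line %d", path, bad[1]),
                 sprintf("require 0 <= start < end, got start=%d end=%d",
                         start[bad[1]], end[bad[1]]))
  }
  strand <- m[, 6]
  if (assume_plus_strand) strand[strand == "."] <- "+"
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop_located("BED validation error", sprintf("%s line %d", path, bad[1]),
                 sprintf("unstranded or invalid strand '%s' (set assume_plus_strand = TRUE to map '.' to '+')",
                         strand[bad[1]]))
  }
  data.frame(chrom = m[, 1], start = start, end = end, strand = strand,
             read_id = m[, 4], ago_source = source_label,
             stringsAsFactors = FALSE)
}

#' Write intervals to a BED6 file
#'
#' @param df Data.frame with `chrom`, `start`, `end`, `strand` plus `name`
#'   and `score` columns (defaulted if absent).
#' @param path Output path.
#' @param name,score Column names to use for BED name/score fields.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path, name = "name", score = "score") {
  validate_intervals(df, "BED")
  nm <- if (name %in% names(df)) df[[name]] else rep(".", nrow(df))
  sc <- if (score %in% names(df)) df[[score]] else rep(0L, nrow(df))
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                 df$chrom, df$start, df$end, nm, as.character(sc), df$strand)
  writeLines(out, path)
  invisible(path)
}
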