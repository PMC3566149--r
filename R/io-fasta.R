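#' Read sequences from a FASTA file with alphabet normalization
#'
#' Records are upper-cased and normalized to the requested alphabet on read:
#' `alphabet = "rna"` maps T to U (mature miRNA files are distributed in
#' either alphabet), `alphabet = "dna"` maps U to T (genomic/transcript
#' sequence). Multi-line records are concatenated.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"rna"` or `"dna"`.
#' @return Named character vector of sequences (names are record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_located("FASTA validation error", path,
                 paste0("duplicate record ids: ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- normalize_alphabet(seqs, alphabet)
  bad <- grepl(if (alphabet == "rna") "[^ACGUN]" else "[^ACGTN]", seqs)
  if (any(bad)) {
    stop_located("FASTA validation error", ids[which(bad)[1]],
                 "sequence contains characters outside {A,C,G,U/T,N}")
  }
  if (any(!nzchar(seqs))) {
    stop_located("FASTA validation error", ids[which(!nzchar(seqs))[1]],
                 "empty sequence")
  }
  stats::setNames(seqs, ids)
}

normalize_alphabet <- function(seqs, alphabet) {
  if (alphabet == "rna") chartr("T", "U", toupper(seqs))
  else chartr("U", "T", toupper(seqs))
}

#' Write a named vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' @param seq Character vector of DNA or RNA sequences.
#' @param alphabet Output alphabet; `"auto"` (default) keeps RNA for inputs
#'   containing U and DNA otherwise.
#' @return Reverse complements.
#' @export
revcomp <- function(seq, alphabet = c("auto", "dna", "rna")) {
  alphabet <- match.arg(alphabet)
  up <- toupper(seq)
  comp <- chartr("ACGTUN", "TGCAAN", up)
  as_rna <- switch(alphabet,
                   auto = grepl("U", up, fixed = TRUE),
                   dna = rep(FALSE, length(seq)),
                   rna = rep(TRUE, length(seq)))
  comp[as_rna] <- chartr("T", "U", comp[as_rna])
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' Spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in 5'-to-3' transcript orientation
#' (reverse-complemented for minus-strand transcripts).
#'
#' @param genome Named character vector of chromosome sequences (DNA).
#' @param transcripts A `transcript_set`.
#' @return Named character vector of spliced transcript sequences (DNA).
#' @export
transcript_sequences <- function(genome, transcripts) {
  ids <- unique(transcripts$transcript_id)
  out <- vapply(ids, function(tid) {
    ex <- transcripts[transcripts$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    chromseq <- genome[[ex$chrom[1]]]
    pieces <- substring(chromseq, ex$start + 1L, ex$end)
    s <- paste(pieces, collapse = "")
    if (ex$strand[1] == "-") s <- revcomp(s)
    s
  }, "")
  stats::setNames(out, ids)
}
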