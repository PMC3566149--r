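# Small in-code fixture builders.

mk_reads <- function(start, end, chrom = "chr1", strand = "+",
                     source = "Ago1", id = NULL) {
  n <- max(length(start), length(end))
  start <- rep_len(start, n); end <- rep_len(end, n)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n),
             read_id = if (is.null(id)) sprintf("r%03d", seq_len(n)) else id,
             ago_source = rep_len(source, n), stringsAsFactors = FALSE)
}

# n random 32-nt reads over a toy chromosome, mixed strands and sources.
random_reads <- function(n, chrom_len = 2000, read_len = 32,
                         chroms = "chr1", strands = c("+", "-"),
                         sources = paste0("Ago", 1:4)) {
  start <- sample.int(chrom_len - read_len, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + read_len,
             strand = sample(strands, n, replace = TRUE),
             read_id = sprintf("r%05d", seq_len(n)),
             ago_source = sample(sources, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

mk_tx <- function(id, exons, strand = "+", chrom = "chr1",
                  biotype = "lincRNA", gene = paste0("g_", id)) {
  as_transcript_set(data.frame(
    transcript_id = id, gene_id = gene, biotype = biotype, chrom = chrom,
    strand = strand, start = vapply(exons, `[`, 0, 1),
    end = vapply(exons, `[`, 0, 2), stringsAsFactors = FALSE))
}

mk_element <- function(start, end, chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             cluster_id = sprintf("%s:%d-%d:%s", chrom, start, end, strand),
             max_depth = 5L, total_support = 5L, support_Ago1 = 5L,
             stringsAsFactors = FALSE)
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
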