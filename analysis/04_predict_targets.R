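#!/usr/bin/env Rscript

# Step 4: identify the cognate miRNA for every annotated cluster.
#
# Extracts each cluster's site sequence (plus 15 nt of flank) from the
# spliced transcript, aligns every miRNA with the seed-weighted duplex
# scorer and keeps hits with score >= 160 and hybridization energy
# <= -20 kcal/mol. Writes results/hits.tsv.

suppressPackageStartupMessages(library(mrenet))

data_dir <- file.path("results", "data")
annotations <- utils::read.table(file.path("results", "annotations.tsv"),
                                 sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
transcripts <- read_gtf(file.path(data_dir, "transcripts.gtf"))
genome <- read_fasta(file.path(data_dir, "genome.fa"), "dna")
mirnas <- read_fasta(file.path(data_dir, "mirnas.fa"), "rna")

tx_seqs <- transcript_sequences(genome, transcripts)
sites <- extract_sites(annotations, tx_seqs, flank = 15L)
hits <- predict_targets(mirnas, sites)

utils::write.table(
  hits[, setdiff(names(hits), c("mirna_aln", "pair_line", "target_aln"))],
  file.path("results", "hits.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

cat(sprintf("%d candidate sites -> %d hits (score %s, energy %s)\n",
            nrow(sites), nrow(hits),
            paste(range(hits$score), collapse = ".."),
            paste(range(round(hits$energy, 1)), collapse = "..")))
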