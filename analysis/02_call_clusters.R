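#!/usr/bin/env Rscript

# Step 2: call miRNA recognition elements from the mapped reads.
#
# Merges the four Argonaute BED libraries and calls maximal contiguous runs
# of merged coverage >= 5, with per-library support counts. Writes
# results/clusters.bed and results/cluster_support.tsv.

suppressPackageStartupMessages(library(mrenet))

data_dir <- file.path("results", "data")
sources <- paste0("Ago", 1:4)
read_sets <- lapply(stats::setNames(sources, sources), function(s)
  read_bed(file.path(data_dir, paste0("reads_", s, ".bed")), s))
reads <- merge_sources(read_sets)

elements <- call_clusters(reads, min_depth = 5L, sources = sources)

bed <- elements
bed$name <- elements$cluster_id
bed$score <- elements$max_depth
write_bed(bed, file.path("results", "clusters.bed"))
utils::write.table(
  elements[, c("cluster_id", "max_depth", "total_support",
               paste0("support_", sources))],
  file.path("results", "cluster_support.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d reads -> %d clusters (max depth %d)\n",
            nrow(reads), nrow(elements), max(elements$max_depth)))
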