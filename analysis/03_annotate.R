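#!/usr/bin/env Rscript

# Step 3: intersect called clusters with the transcript annotation.
#
# Assigns every cluster to overlapping exons in spliced transcript
# coordinates and tabulates exon/transcript/gene counts per biotype class.
# Writes results/annotations.tsv and results/annotation_counts.tsv.

suppressPackageStartupMessages(library(mrenet))

elements <- read_bed(file.path("results", "clusters.bed"), "merged")
names(elements)[names(elements) == "read_id"] <- "cluster_id"
transcripts <- read_gtf(file.path("results", "data", "transcripts.gtf"))

annotations <- assign_clusters(elements, transcripts)
counts <- count_overlaps(annotations)

utils::write.table(annotations, file.path("results", "annotations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(counts, file.path("results", "annotation_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d clusters -> %d exon annotations on %d transcripts\n",
            nrow(elements), nrow(annotations),
            length(unique(annotations$transcript_id))))
print(counts)
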