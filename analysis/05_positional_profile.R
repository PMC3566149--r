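#!/usr/bin/env Rscript

# Step 5: profile cluster positions along lncRNA transcripts.
#
# Bins every lncRNA cluster annotation into ten 10% bins of normalized
# transcript length by the midpoint rule. Writes results/bins.tsv.

suppressPackageStartupMessages(library(mrenet))

annotations <- utils::read.table(file.path("results", "annotations.tsv"),
                                 sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
transcripts <- read_gtf(file.path("results", "data", "transcripts.gtf"))

lnc <- annotations[annotations$biotype_class == "lncRNA", , drop = FALSE]
profile <- bin_elements(lnc, transcripts, n_bins = 10L)
write_profile(profile, file.path("results", "bins.tsv"))

print(profile)
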