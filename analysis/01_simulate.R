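#!/usr/bin/env Rscript

# Step 1: generate the synthetic PAR-CLIP study inputs.
#
# Writes a deterministic bundle (toy genome, transcript models, mature
# miRNAs, four Argonaute read libraries, validated miRNA-mRNA pairs and the
# ground-truth site manifest) under results/data/.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>]

suppressPackageStartupMessages(library(mrenet))

args <- commandArgs(trailingOnly = TRUE)
i <- which(args == "--seed")
seed <- if (length(i) == 1 && i < length(args)) as.integer(args[i + 1]) else 13L

cfg <- synthetic_config(seed = seed)
bundle <- generate_bundle(cfg)
dir <- file.path("results", "data")
write_bundle(bundle, dir)

cat(sprintf("seed %d: %d transcripts, %d miRNAs, %d planted sites, %d reads\n",
            seed, length(unique(bundle$transcripts$transcript_id)),
            length(bundle$mirnas), nrow(bundle$truth$sites),
            nrow(bundle$reads)))
cat("wrote", dir, "\n")
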