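#!/usr/bin/env Rscript

# Step 6: assemble the miRNA-lncRNA-mRNA interaction network.
#
# Joins the predicted hits with the validated miRNA-mRNA pairs into an
# unweighted tripartite network. Writes results/network.tsv (canonical),
# results/network.sif, results/network.graphml and
# results/network_stats.tsv.

suppressPackageStartupMessages(library(mrenet))

hits <- utils::read.table(file.path("results", "hits.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
validated <- utils::read.table(file.path("results", "data", "validated.tsv"),
                               sep = "\t", header = TRUE,
                               colClasses = "character")

net <- build_network(hits[hits$biotype_class == "lncRNA", ],
                     hits[hits$biotype_class == "mRNA", ], validated)
write_network(net, file.path("results", "network.tsv"), "tsv")
write_network(net, file.path("results", "network.sif"), "sif")
write_network(net, file.path("results", "network.graphml"), "graphml")

st <- network_stats(net)
utils::write.table(
  data.frame(metric = c(paste0("nodes_", names(st$n_nodes)), "edges",
                        "components", "largest_component"),
             value = c(as.integer(st$n_nodes), nrow(net$edges),
                       length(st$component_sizes),
                       max(st$component_sizes))),
  file.path("results", "network_stats.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("network: %d miRNA / %d lncRNA / %d mRNA nodes, %d edges, %d component(s)\n",
            st$n_nodes[["miRNA"]], st$n_nodes[["lncRNA"]],
            st$n_nodes[["mRNA"]], nrow(net$edges),
            length(st$component_sizes)))
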