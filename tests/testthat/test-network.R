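mk_hits <- function(mirna, tx) {
  data.frame(mirna_id = mirna, transcript_id = tx, stringsAsFactors = FALSE)
}

test_that("edges deduplicate and evidence labels join predictions with validations", {
  lnc <- mk_hits(c("miR-a", "miR-a"), c("lnc1", "lnc1"))    # 2 hits, 1 edge
  mrna <- mk_hits("miR-a", "tx1")
  val <- data.frame(mirna_id = "miR-a", transcript_id = "tx1",
                    stringsAsFactors = FALSE)
  net <- build_network(lnc, mrna, val)
  expect_equal(nrow(net$edges), 2L)
  e <- net$edges[net$edges$target == "tx1", ]
  expect_equal(e$evidence, "both")
  expect_equal(net$edges$evidence[net$edges$target == "lnc1"], "predicted")

  # validated-only pairs are added as mRNA edges
  val2 <- rbind(val, data.frame(mirna_id = "miR-z", transcript_id = "tx9"))
  net2 <- build_network(lnc, mrna, val2)
  expect_equal(net2$edges$evidence[net2$edges$target == "tx9"], "validated")

  # disjoint inputs just union
  net3 <- build_network(mk_hits(paste0("m", 1:3), paste0("L", 1:3)),
                        mk_hits(paste0("m", 4:7), paste0("T", 1:4)))
  expect_equal(nrow(net3$edges), 7L)

  empty <- build_network()
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)

  # a validated pair naming a lncRNA-typed transcript is a class conflict
  bad <- data.frame(mirna_id = "miR-q", transcript_id = "lnc1")
  expect_error(build_network(lnc, mrna, bad), "class conflict")
})

test_that("edge counts decompose into predicted lncRNA, predicted mRNA and validated-only", {
  set.seed(12)
  lnc <- mk_hits(sample(paste0("m", 1:6), 20, TRUE),
                 sample(paste0("L", 1:5), 20, TRUE))
  mrna <- mk_hits(sample(paste0("m", 1:6), 20, TRUE),
                  sample(paste0("T", 1:5), 20, TRUE))
  val <- unique(mk_hits(sample(paste0("m", 1:8), 10, TRUE),
                        sample(paste0("T", 1:8), 10, TRUE)))
  net <- build_network(lnc, mrna, val)
  n_lnc <- nrow(unique(lnc))
  n_mrna <- nrow(unique(mrna))
  pred_keys <- paste(mrna$mirna_id, mrna$transcript_id)
  n_val_only <- sum(!paste(val$mirna_id, val$transcript_id) %in% pred_keys)
  expect_equal(nrow(net$edges), n_lnc + n_mrna + n_val_only)
})

test_that("network statistics report typed node counts, degrees and components", {
  star <- build_network(mk_hits("m1", "L1"),
                        mk_hits(c("m1", "m1"), c("T1", "T2")))
  st <- network_stats(star)
  expect_equal(unname(st$n_nodes[["miRNA"]]), 1L)
  expect_equal(length(st$component_sizes), 1L)
  expect_equal(unname(st$degree[["m1"]]), 3L)

  two <- build_network(mk_hits("m1", "L1"), mk_hits("m2", "T1"))
  expect_equal(length(network_stats(two)$component_sizes), 2L)

  zero <- network_stats(build_network())
  expect_equal(sum(zero$n_nodes), 0L)
})

test_that("component structure matches a union-find oracle on random bipartite graphs", {
  set.seed(3)
  for (rep in 1:10) {
    mirs <- paste0("m", 1:50)
    txs <- paste0("t", 1:100)
    pairs <- expand.grid(mirna_id = mirs, transcript_id = txs,
                         stringsAsFactors = FALSE)
    pairs <- pairs[runif(nrow(pairs)) < 0.02, ]
    tx_class <- stats::setNames(sample(c("lnc", "mrna"), length(txs), TRUE), txs)
    cls <- unname(tx_class[pairs$transcript_id])
    net <- build_network(pairs[cls == "lnc", ], pairs[cls == "mrna", ])
    st <- network_stats(net)
    want <- oracle_components(net$nodes$id,
                              data.frame(source = net$edges$source,
                                         target = net$edges$target))
    expect_equal(length(st$component_sizes), want$n_components)
    expect_equal(sort(st$component_sizes), want$sizes)
  }
})

test_that("neighborhood extraction is an induced subgraph by graph distance", {
  # path of length 4: m1-L1, m2-L1, m2-L2, m3-L2
  net <- build_network(mk_hits(c("m1", "m2", "m2", "m3"),
                               c("L1", "L1", "L2", "L2")))
  expect_equal(neighborhood(net, "m1", 0)$nodes$id, "m1")
  nb1 <- neighborhood(net, "m1", 1)
  expect_setequal(nb1$nodes$id, c("m1", "L1"))
  nb2 <- neighborhood(net, "m1", 2)           # from a path end, radius 2
  expect_setequal(nb2$nodes$id, c("m1", "L1", "m2"))

  star <- build_network(mk_hits(c("m1", "m1", "m1"), c("L1", "L2", "L3")))
  expect_equal(nrow(neighborhood(star, "m1", 1)$nodes), 4L)
  expect_error(neighborhood(net, "nope", 1), "unknown node")
})

test_that("every lncRNA node traces back to at least one predicted hit", {
  b <- generate_bundle(synthetic_config(seed = 13))
  res <- with(b, {
    el <- call_clusters(reads[, 1:6], sources = paste0("Ago", 1:4))
    ann <- assign_clusters(el, transcripts)
    sites <- extract_sites(ann, transcript_sequences(genome, transcripts))
    hits <- predict_targets(mirnas, sites)
    net <- build_network(hits[hits$biotype_class == "lncRNA", ],
                         hits[hits$biotype_class == "mRNA", ], validated)
    list(hits = hits, net = net)
  })
  lnc_nodes <- res$net$nodes$id[res$net$nodes$type == "lncRNA"]
  expect_true(all(lnc_nodes %in%
                    res$hits$transcript_id[res$hits$biotype_class == "lncRNA"]))
  expect_gt(length(lnc_nodes), 0L)
})
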