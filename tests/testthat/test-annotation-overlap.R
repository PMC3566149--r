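test_that("genomic-to-transcript mapping accumulates exon lengths and reverses on minus strand", {
  plus <- mk_tx("t1", list(c(100, 200), c(300, 400)), strand = "+")
  expect_equal(genomic_to_transcript(plus, 100L), 0L)
  expect_equal(genomic_to_transcript(plus, 300L), 100L)
  expect_error(genomic_to_transcript(plus, 250L), "intronic")

  minus <- mk_tx("t2", list(c(100, 200), c(300, 400)), strand = "-")
  expect_equal(genomic_to_transcript(minus, 399L), 0L)

  # oracle: enumerate exonic bases; 3'->5' genomic order on minus strand
  bases <- c(100:199, 300:399)
  expect_equal(genomic_to_transcript(minus, bases), rev(seq_along(bases)) - 1L)
  expect_equal(genomic_to_transcript(plus, bases), seq_along(bases) - 1L)
})

test_that("spliced-coordinate round-trip is the identity on every exonic base", {
  set.seed(3)
  for (strand in c("+", "-")) {
    tx <- mk_tx("t", list(c(10, 35), c(50, 61), c(90, 140)), strand = strand)
    tpos <- 0:(sum(tx$end - tx$start) - 1L)
    g <- transcript_to_genomic(tx, tpos)
    expect_equal(genomic_to_transcript(tx, g), tpos)
  }
})

test_that("cluster assignment clips to exonic overlap in transcript coordinates", {
  tx <- mk_tx("t1", list(c(100, 200)))
  ann <- assign_clusters(mk_element(150, 160), tx)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$tx_start, 50L)
  expect_equal(ann$tx_end, 60L)
  expect_equal(ann$exon_index, 0L)
  expect_equal(ann$biotype_class, "lncRNA")

  # intronic element -> no annotation
  tx2 <- mk_tx("t2", list(c(100, 200), c(300, 400)))
  expect_equal(nrow(assign_clusters(mk_element(210, 260), tx2)), 0L)

  # element spanning the junction region annotates both exons with adjacent spans
  ann2 <- assign_clusters(mk_element(180, 320), tx2)
  expect_equal(nrow(ann2), 2L)
  expect_equal(ann2$exon_index, c(0L, 1L))
  expect_equal(ann2$tx_start, c(80L, 100L))
  expect_equal(ann2$tx_end, c(100L, 120L))
  expect_equal(ann2$tx_end[1], ann2$tx_start[2])
})

test_that("strand matching is applied by default and can be relaxed", {
  tx <- mk_tx("t1", list(c(100, 200)), strand = "-")
  el <- mk_element(150, 160, strand = "+")
  expect_equal(nrow(assign_clusters(el, tx)), 0L)
  relaxed <- assign_clusters(el, tx, same_strand = FALSE)
  expect_equal(nrow(relaxed), 1L)
  # spans are still reported in transcript (minus-strand) orientation
  expect_equal(relaxed$tx_start, 100L - 60L)
  expect_equal(relaxed$tx_end, 100L - 50L)
})

test_that("assignment equals the base-set intersection oracle on random layouts", {
  set.seed(11)
  for (rep in 1:10) {
    txs <- do.call(rbind, lapply(1:6, function(i) {
      n_ex <- sample(1:3, 1)
      offset <- (i - 1) * 1000 + sample(0:50, 1)
      starts <- offset + cumsum(sample(30:120, n_ex)) +
        c(0, cumsum(sample(40:90, max(0, n_ex - 1))))[seq_len(n_ex)]
      mk_tx(sprintf("t%02d_%d", i, rep),
            Map(c, starts, starts + sample(20:60, n_ex, TRUE)),
            strand = sample(c("+", "-"), 1),
            biotype = sample(c("lincRNA", "protein_coding"), 1))
    }))
    class(txs) <- c("transcript_set", "data.frame")
    els <- do.call(rbind, lapply(1:15, function(k) {
      s <- sample(0:6200, 1)
      mk_element(s, s + sample(10:80, 1), strand = sample(c("+", "-"), 1))
    }))
    got <- assign_clusters(els, txs)
    want <- oracle_assign(els, txs)
    cols <- c("cluster_id", "transcript_id", "exon_index", "tx_start", "tx_end")
    expect_equal(got[, cols], want[, cols])
  }
})

test_that("assignment is invariant under whole-genome translation", {
  set.seed(5)
  tx <- mk_tx("t1", list(c(100, 220), c(400, 490)), strand = "-")
  els <- rbind(mk_element(110, 150, strand = "-"),
               mk_element(200, 430, strand = "-"))
  base <- assign_clusters(els, tx)
  shift <- 1234L
  tx2 <- tx; tx2$start <- tx$start + shift; tx2$end <- tx$end + shift
  els2 <- els; els2$start <- els$start + shift; els2$end <- els$end + shift
  els2$cluster_id <- els$cluster_id
  shifted <- assign_clusters(els2, tx2)
  expect_equal(shifted[, c("tx_start", "tx_end", "exon_index")],
               base[, c("tx_start", "tx_end", "exon_index")])
})

test_that("overlap counting is by distinct exons, transcripts and clusters", {
  ann <- data.frame(
    cluster_id = c("c1", "c2", "c2"),
    transcript_id = c("t1", "t1", "t2"),
    gene_id = c("g1", "g1", "g2"),
    biotype = c("lincRNA", "lincRNA", "protein_coding"),
    biotype_class = c("lncRNA", "lncRNA", "mRNA"),
    exon_index = c(0L, 0L, 1L), tx_start = c(0L, 5L, 0L),
    tx_end = c(10L, 15L, 10L), stringsAsFactors = FALSE)
  cnt <- count_overlaps(ann)
  expect_equal(cnt$n_exons[cnt$biotype_class == "lncRNA"], 1L)
  expect_equal(cnt$n_clusters[cnt$biotype_class == "lncRNA"], 2L)
  expect_equal(cnt$n_transcripts[cnt$biotype_class == "mRNA"], 1L)

  zero <- count_overlaps(ann[0, ])
  expect_equal(zero$n_exons, c(0L, 0L))
  expect_equal(zero$n_clusters, c(0L, 0L))
})

test_that("with no noise the lncRNA exon count equals the planted distinct exons", {
  b <- generate_bundle(synthetic_config(seed = 19, n_mrna = 0,
                                        n_planted_sites = 12))
  el <- call_clusters(b$reads[, 1:6])
  ann <- assign_clusters(el, b$transcripts)
  cnt <- count_overlaps(ann)
  planted_exons <- unique(paste(b$truth$sites$transcript_id,
                                b$truth$sites$exon_index))
  expect_equal(cnt$n_exons[cnt$biotype_class == "lncRNA"],
               length(planted_exons))
})
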