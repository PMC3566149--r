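test_that("merge_sources pools reads, keeps tags and rejects duplicate ids per source", {
  r1 <- mk_reads(100, 132, source = "Ago1", id = "r1")
  r2 <- mk_reads(200, 232, source = "Ago2", id = "r1")
  merged <- merge_sources(list(Ago1 = r1, Ago2 = r2))
  expect_equal(nrow(merged), 2L)
  expect_equal(sort(merged$ago_source), c("Ago1", "Ago2"))
  # same read id under two sources is two distinct records
  expect_equal(merged$read_id, c("r1", "r1"))

  expect_equal(nrow(merge_sources(list(Ago1 = mk_reads(integer(), integer())))), 0L)
  expect_error(merge_sources(list(Ago1 = rbind(r1, r1))),
               "duplicate \\(read_id, source\\)")
})

test_that("pileup run-length encodes per-base depth and conserves mapped bases", {
  reads <- mk_reads(c(100, 116), c(132, 148))
  p <- pileup(reads)
  expect_equal(p$start, c(100L, 116L, 132L))
  expect_equal(p$end, c(116L, 132L, 148L))
  expect_equal(p$depth, c(1L, 2L, 1L))
  expect_equal(sum((p$end - p$start) * p$depth), sum(reads$end - reads$start))

  expect_equal(nrow(pileup(mk_reads(integer(), integer()))), 0L)

  five <- mk_reads(rep(100, 5), rep(132, 5))
  p5 <- pileup(five)
  expect_equal(p5, data.frame(start = 100L, end = 132L, depth = 5L))
})

test_that("five identical reads form one element at the depth-5 boundary; four form none", {
  five <- mk_reads(rep(100, 5), rep(132, 5))
  el <- call_clusters(five, min_depth = 5)
  expect_equal(nrow(el), 1L)
  expect_equal(el$start, 100L)
  expect_equal(el$end, 132L)
  expect_equal(el$max_depth, 5L)
  expect_equal(el$cluster_id, "chr1:100-132:+")
  expect_equal(el$support_Ago1, 5L)

  four <- mk_reads(rep(100, 4), rep(132, 4))
  expect_equal(nrow(call_clusters(four, min_depth = 5)), 0L)
  expect_error(call_clusters(five, min_depth = 0), "min_depth")
})

test_that("calling is stranded by default and pooled with ignore_strand", {
  reads <- rbind(mk_reads(rep(100, 3), rep(132, 3), strand = "+"),
                 mk_reads(rep(100, 3), rep(132, 3), strand = "-",
                          id = sprintf("m%d", 1:3)))
  expect_equal(nrow(call_clusters(reads, min_depth = 5)), 0L)
  pooled <- call_clusters(reads, min_depth = 5, ignore_strand = TRUE)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$max_depth, 6L)
})

test_that("cluster calling equals the per-base brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:25) {
    reads <- random_reads(sample(100:1500, 1), chrom_len = 2500,
                          chroms = c("chr1", "chr2"))
    cov_oracle <- NULL
    for (md in c(1L, 2L, 5L, 10L)) {
      got <- call_clusters(reads, min_depth = md,
                           sources = paste0("Ago", 1:4))
      want <- oracle_call_clusters(reads, md, sources = paste0("Ago", 1:4))
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        cols <- c("chrom", "start", "end", "strand", "max_depth",
                  "total_support", paste0("support_Ago", 1:4))
        expect_equal(got[, cols], want[, cols])
      }
    }
  }
})

test_that("elements are maximal, monotone in min_depth, and cover all reads at depth 1", {
  set.seed(7)
  reads <- random_reads(400, chrom_len = 1000)
  prev <- NULL
  for (md in c(1L, 2L, 5L, 10L)) {
    el <- call_clusters(reads, md)
    # maximality: depth immediately before/after each run is < min_depth
    for (key in unique(paste(el$chrom, el$strand))) {
      g <- reads[paste(reads$chrom, reads$strand) == key, ]
      e <- el[paste(el$chrom, el$strand) == key, ]
      depth_at <- function(pos) sum(g$start <= pos & g$end > pos)
      expect_true(all(vapply(e$start - 1L, depth_at, 0) < md))
      expect_true(all(vapply(e$end, depth_at, 0) < md))
    }
    if (!is.null(prev)) {
      # raising the threshold can only shrink the covered bases (a plateau
      # may split one run into several, so element counts are not monotone)
      expect_lte(sum(el$end - el$start), sum(prev$end - prev$start))
      # every element at the higher threshold lies inside one at the lower
      for (k in seq_len(nrow(el))) {
        within <- prev$chrom == el$chrom[k] & prev$strand == el$strand[k] &
          prev$start <= el$start[k] & prev$end >= el$end[k]
        expect_equal(sum(within), 1L)
      }
    }
    prev <- el
  }
  # with min_depth = 1 the union of elements equals the union of read spans
  el1 <- call_clusters(reads, 1L)
  for (key in unique(paste(reads$chrom, reads$strand))) {
    g <- reads[paste(reads$chrom, reads$strand) == key, ]
    e <- el1[paste(el1$chrom, el1$strand) == key, ]
    covered <- sort(unique(unlist(Map(seq, g$start, g$end - 1L))))
    runs <- sort(unique(unlist(Map(seq, e$start, e$end - 1L))))
    expect_equal(runs, covered)
  }
})

test_that("per-Ago contribution summary counts supported lncRNA elements and cognate miRNAs", {
  el <- mk_element(100, 140)
  el$support_Ago2 <- 0L
  ann <- data.frame(cluster_id = el$cluster_id, transcript_id = "t1",
                    gene_id = "g1", biotype = "lincRNA",
                    biotype_class = "lncRNA", exon_index = 0L,
                    tx_start = 0L, tx_end = 40L, stringsAsFactors = FALSE)
  hits <- data.frame(mirna_id = "miR-x", cluster_id = el$cluster_id,
                     transcript_id = "t1", stringsAsFactors = FALSE)
  s <- summarize_ago_contributions(el, ann, hits, sources = c("Ago1", "Ago2"))
  expect_equal(s$summary$n_elements, c(1L, 0L))
  expect_equal(s$summary$n_transcripts, c(1L, 0L))
  expect_equal(s$summary$mirnas[[1]], "miR-x")
  expect_equal(s$summary$mirnas[[2]], character(0))
  expect_equal(unname(s$presence[1, ]), c(TRUE, FALSE))

  z <- summarize_ago_contributions(el[0, ], ann[0, ], hits[0, ],
                                   sources = c("Ago1", "Ago2"))
  expect_equal(z$summary$n_elements, c(0L, 0L))
})

test_that("uniform source assignment yields identical per-Ago rows on synthetic data", {
  b <- generate_bundle(synthetic_config(seed = 21, n_planted_sites = 8,
                                        site_depth = c(40L, 40L)))
  el <- call_clusters(b$reads[, 1:6], sources = paste0("Ago", 1:4))
  ann <- assign_clusters(el, b$transcripts)
  s <- summarize_ago_contributions(el, ann, hits = NULL)
  # depth 40 per site: every Ago supports every element almost surely
  expect_true(all(s$presence))
  expect_equal(length(unique(s$summary$n_elements)), 1L)
  expect_equal(length(unique(s$summary$n_transcripts)), 1L)
})
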