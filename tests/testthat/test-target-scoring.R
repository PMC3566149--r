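test_that("a perfect 22-nt complement scores 215 under default parameters", {
  set.seed(1)
  for (rep in 1:5) {
    mir <- rand_rna(22)
    a <- align_duplex(mir, revcomp(mir, "rna"))
    # 22 Watson-Crick pairs at +5, 7 of them in the seed scaled x4
    expect_equal(a$score, 5 * 22 + (4 - 1) * 5 * 7)
    expect_equal(a$pair_line, strrep("|", 22))
    expect_gte(a$score, scoring_params()$score_min)
  }
})

test_that("one seed G:U wobble lowers the perfect-site score by exactly 16", {
  # fixed 22-nt miRNAs with a G or U at a chosen seed position; for random
  # sequences a gapped realignment can occasionally beat the straight wobble
  # duplex, so the closed form is asserted on canonical instances
  mirs <- c("UGAGGUAGUAGGUUGUAUAGUU", "UAGCUUAUCAGACUGAUGUUGA",
            "CAUUGCACUUGUCUCGGUCUGA", "UACCCUGUAGAACCGAAUUUGU",
            "UCCCUGAGACCCUAACUUGUGA")
  pos <- c(2L, 3L, 3L, 6L, 5L)
  for (k in seq_along(mirs)) {
    mir <- mirs[k]
    m <- strsplit(mir, "")[[1]]
    site <- strsplit(revcomp(mir, "rna"), "")[[1]]
    tpos <- 22L - pos[k] + 1L         # column pairing miRNA position pos[k]
    site[tpos] <- if (m[pos[k]] == "G") "U" else "G"
    a <- align_duplex(mir, paste(site, collapse = ""))
    expect_equal(a$score, 215 - (5 - 1) * 4)
    expect_equal(substr(a$pair_line, tpos, tpos), ":")
  }
})

test_that("local alignment floors at zero when no complementarity exists", {
  a <- align_duplex(strrep("A", 22), strrep("A", 30))
  expect_equal(a$score, 0)
  expect_equal(a$mirna_aln, "")
  expect_error(align_duplex("ACGUA", strrep("A", 30)), "at least 6 nt")
})

test_that("the aligner equals the exhaustive oracle on short sequence pairs", {
  set.seed(4)
  params <- scoring_params()
  for (rep in 1:40) {
    n <- sample(6:12, 1); m <- sample(6:12, 1)
    mir <- rand_rna(n); site <- rand_rna(m)
    got <- align_duplex(mir, site, params)$score
    expect_equal(got, oracle_duplex_score(mir, site, params),
                 info = paste(mir, site))
  }
  # and the recursion oracle itself matches pure enumeration on tiny inputs
  for (rep in 1:8) {
    mir <- rand_rna(6); site <- rand_rna(7)
    expect_equal(oracle_duplex_score(mir, site, params),
                 max(0, oracle_duplex_enumerate(mir, site, params)))
  }
})

test_that("score is invariant to flank extension beyond the aligned region", {
  set.seed(6)
  mir <- rand_rna(22)
  core <- revcomp(mir, "rna")
  base <- align_duplex(mir, core)$score
  padded <- paste0(strrep("A", 15), core, strrep("A", 15))
  expect_equal(align_duplex(mir, padded)$score, base)
})

test_that("duplex energy is stabilized by stacks and destabilized by defects", {
  tbl <- nn_energy_table()
  # GC-rich perfect 22-mer clears the -20 kcal/mol gate
  mir <- paste(rep(c("G", "C"), 11), collapse = "")
  a <- align_duplex(mir, revcomp(mir, "rna"))
  expect_lte(duplex_energy(a, tbl), -20)

  # one internal mismatch strictly raises the energy
  set.seed(8)
  for (rep in 1:5) {
    mir <- rand_rna(22)
    site <- strsplit(revcomp(mir, "rna"), "")[[1]]
    perfect <- duplex_energy(align_duplex(mir, paste(site, collapse = "")), tbl)
    k <- sample(8:14, 1)
    m <- strsplit(mir, "")[[1]][22 - k + 1]
    site[k] <- setdiff(c("A", "C", "G", "U"),
                       c(site[k], if (m == "G") "U", if (m == "U") "G"))[1]
    broken <- duplex_energy(align_duplex(mir, paste(site, collapse = "")), tbl)
    expect_gt(broken, perfect)
  }

  # a 2-bp duplex cannot reach -20
  two <- structure(list(score = 40, mirna_aln = "CG", pair_line = "||",
                        target_aln = "GC", target_start = 0L,
                        target_end = 2L, mirna_start = 20L, mirna_end = 22L),
                   class = "duplex_alignment")
  expect_gt(duplex_energy(two, tbl), -20)

  # appending a Watson-Crick stack never raises the energy
  for (len in 8:21) {
    m1 <- substr("GCAUGGCAUCGAUCGGAUCCGA", 1, len)
    e1 <- duplex_energy(align_duplex(m1, revcomp(m1, "rna")), tbl)
    m2 <- substr("GCAUGGCAUCGAUCGGAUCCGA", 1, len + 1)
    e2 <- duplex_energy(align_duplex(m2, revcomp(m2, "rna")), tbl)
    expect_lte(e2, e1)
  }

  expect_error(
    duplex_energy(structure(list(pair_line = "  ", mirna_aln = "AC",
                                 target_aln = "GG"),
                            class = "duplex_alignment"), tbl),
    "no paired columns")
})

test_that("site extraction clips flanks at transcript bounds", {
  tx_seq <- rand_dna(200)
  ann <- data.frame(cluster_id = "c1", transcript_id = "t1",
                    tx_start = 50L, tx_end = 82L, stringsAsFactors = FALSE)
  expect_equal(nchar(extract_site(tx_seq, ann, flank = 0L)$seq), 32L)
  expect_equal(nchar(extract_site(tx_seq, ann, flank = 15L)$seq), 62L)
  ann0 <- transform(ann, tx_start = 0L, tx_end = 32L)
  s <- extract_site(tx_seq, ann0, flank = 15L)
  expect_equal(s$site_start, 0L)
  expect_equal(nchar(s$seq), 47L)
  annbad <- transform(ann, tx_end = 300L)
  expect_error(extract_site(tx_seq, annbad), "outside sequence")
})

test_that("prediction applies both thresholds conjunctively and finds only planted miRNAs", {
  set.seed(7)
  mir_x <- rand_rna(22)
  mir_y <- paste(sample(strsplit(mir_x, "")[[1]]), collapse = "")  # scrambled
  site <- data.frame(site_id = "s1", cluster_id = "c1",
                     transcript_id = "t1", biotype_class = "lncRNA",
                     site_start = 10L, site_end = 72L,
                     seq = paste0(rand_rna(15), revcomp(mir_x, "rna"),
                                  rand_rna(15)),
                     stringsAsFactors = FALSE)
  hits <- predict_targets(c("miR-x" = mir_x, "miR-y" = mir_y), site)
  expect_equal(hits$mirna_id, "miR-x")
  expect_gte(hits$score, 160)
  expect_lte(hits$energy, -20)
  # aligned span is reported in transcript coordinates
  expect_equal(hits$tx_start, 10L + 15L)

  expect_equal(nrow(predict_targets(character(0), site)), 0L)

  # raising score_min only removes hits
  stricter <- predict_targets(c("miR-x" = mir_x, "miR-y" = mir_y), site,
                              scoring_params(score_min = 500))
  expect_equal(nrow(stricter), 0L)

  # a site passing the score but failing the energy gate is excluded
  loose <- scoring_params(score_min = 30, energy_max = -20)
  au <- strrep("AU", 4)                      # weak 8-bp A:U duplex
  site_au <- transform(site, seq = paste0(rand_rna(10), revcomp(au, "rna"),
                                          rand_rna(10)))
  aln <- align_duplex(au, site_au$seq, loose)
  if (aln$score >= 30) {
    expect_gt(duplex_energy(aln), -20)
    expect_equal(nrow(predict_targets(c("miR-au" = au), site_au, loose)), 0L)
  }
})
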