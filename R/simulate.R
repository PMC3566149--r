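#' Configuration for the synthetic PAR-CLIP fixture generator
#'
#' The defaults mirror the study conditions the pipeline is built for:
#' 32-nt reads from four Argonaute libraries piling to depth >= 5 over
#' planted miRNA recognition elements on multi-exon transcripts of mixed
#' GENCODE biotypes, with planted sites exactly complementary to a known
#' miRNA set and a tunable 3'-end positional bias.
#'
#' @param seed Integer seed; the bundle is fully deterministic given the seed.
#' @param genome_length Toy chromosome length (nt).
#' @param n_lncrna,n_mrna Transcript counts by class.
#' @param exons_per_tx Integer range (min, max) of exons per transcript.
#' @param exon_length,intron_length,intergenic_gap Integer ranges (nt).
#' @param n_mirnas Number of mature miRNAs (mutually unrelated random
#'   sequences).
#' @param mirna_length Integer range of miRNA lengths (nt).
#' @param n_planted_sites Number of planted recognition elements.
#' @param site_kind `"full_complement"` (site is the exact reverse complement
#'   of a miRNA) or `"seed_only"` (only miRNA positions 2-8 are complemented,
#'   embedded in random context).
#' @param positional_bias Bias beta in `[0, 1]`: each site is constrained to
#'   the final 10% of its transcript with probability beta and placed
#'   uniformly along the transcript otherwise.
#' @param read_length Read length (nt); reads covering a planted site cover
#'   it entirely.
#' @param site_depth Integer range of per-site read depth.
#' @param n_background_reads Uniformly placed noise reads.
#' @param tc_conversion_rate Per-base probability of a PAR-CLIP-style T-to-C
#'   conversion in read sequences (0 disables; converted reads are lost by
#'   exact-match mapping).
#' @param n_sources Number of Argonaute source labels (Ago1..AgoN).
#' @param n_validated Number of validated miRNA-mRNA pairs to emit.
#' @param chrom Chromosome name.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, genome_length = 60000L,
                             n_lncrna = 10L, n_mrna = 5L,
                             exons_per_tx = c(2L, 4L),
                             exon_length = c(150L, 400L),
                             intron_length = c(80L, 300L),
                             intergenic_gap = c(200L, 500L),
                             n_mirnas = 5L, mirna_length = c(20L, 23L),
                             n_planted_sites = 20L,
                             site_kind = c("full_complement", "seed_only"),
                             positional_bias = 0,
                             read_length = 32L, site_depth = c(5L, 20L),
                             n_background_reads = 0L,
                             tc_conversion_rate = 0,
                             n_sources = 4L, n_validated = 2L,
                             chrom = "chrS") {
  site_kind <- match.arg(site_kind)
  assert_that(positional_bias >= 0 && positional_bias <= 1,
              "positional_bias must be in [0, 1]")
  assert_that(read_length > 0L, "read_length must be positive")
  assert_that(site_depth[1] >= 1L, "site_depth minimum must be >= 1")
  assert_that(all(c(n_lncrna, n_mrna, n_mirnas, n_planted_sites,
                    n_background_reads) >= 0L), "counts must be >= 0")
  assert_that(mirna_length[2] <= read_length,
              "miRNA (site) length must not exceed read_length")
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_lncrna = n_lncrna, n_mrna = n_mrna,
                 exons_per_tx = exons_per_tx, exon_length = exon_length,
                 intron_length = intron_length,
                 intergenic_gap = intergenic_gap,
                 n_mirnas = n_mirnas, mirna_length = mirna_length,
                 n_planted_sites = n_planted_sites, site_kind = site_kind,
                 positional_bias = positional_bias,
                 read_length = as.integer(read_length),
                 site_depth = site_depth,
                 n_background_reads = n_background_reads,
                 tc_conversion_rate = tc_conversion_rate,
                 n_sources = n_sources, n_validated = n_validated,
                 chrom = chrom),
            class = "synthetic_config")
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic fixture bundle
#'
#' Produces, deterministically for a given seed, a toy genome with planted
#' recognition elements, transcript models, mature miRNAs, per-Argonaute
#' read sets and a ground-truth manifest that fully determines the expected
#' pipeline output at zero noise.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_bundle` list: `genome` (named DNA vector),
#'   `transcripts` (a `transcript_set`), `mirnas` (named RNA vector),
#'   `reads` (mapped-read data.frame with a `seq` column), `validated`
#'   (data.frame `mirna_id`, `transcript_id`), `truth` (list with `sites`
#'   data.frame and `n_background`), and `config`.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  set.seed(config$seed)
  rl <- config$read_length

  ## transcript layout along one chromosome
  n_tx <- config$n_lncrna + config$n_mrna
  classes <- c(rep("lncRNA", config$n_lncrna), rep("mRNA", config$n_mrna))
  exon_rows <- list()
  cursor <- runif_int(1, config$intergenic_gap)
  for (t in seq_len(n_tx)) {
    n_ex <- runif_int(1, config$exons_per_tx)
    strand <- sample(c("+", "-"), 1)
    biotype <- if (classes[t] == "mRNA") "protein_coding" else
      sample(lnc_biotypes(), 1)
    tid <- sprintf("TX%03d", t)
    gid <- sprintf("G%03d", t)
    for (e in seq_len(n_ex)) {
      len <- runif_int(1, config$exon_length)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gid, biotype = biotype,
        chrom = config$chrom, strand = strand,
        start = cursor, end = cursor + len, stringsAsFactors = FALSE)
      cursor <- cursor + len
      if (e < n_ex) cursor <- cursor + runif_int(1, config$intron_length)
    }
    cursor <- cursor + runif_int(1, config$intergenic_gap)
  }
  if (cursor + rl > config$genome_length) {
    stop("infeasible geometry: transcripts do not fit in genome_length",
         call. = FALSE)
  }
  transcripts <- if (length(exon_rows))
    as_transcript_set(do.call(rbind, exon_rows)) else empty_transcripts()

  ## miRNAs
  mirnas <- character(0)
  if (config$n_mirnas > 0) {
    mirnas <- stats::setNames(
      vapply(seq_len(config$n_mirnas), function(i)
        rand_seq(runif_int(1, config$mirna_length),
                 c("A", "C", "G", "U")), ""),
      sprintf("miR-%02d", seq_len(config$n_mirnas)))
  }

  ## genome sequence (mutable char vector), then plant sites into it
  genome_chars <- sample(c("A", "C", "G", "T"), config$genome_length,
                         replace = TRUE)
  sites <- plant_sites(config, transcripts, mirnas)
  for (k in seq_len(nrow(sites))) {
    sitedna <- site_sequence(mirnas[[sites$mirna_id[k]]], config$site_kind)
    if (sites$strand[k] == "-") sitedna <- revcomp(sitedna, "dna")
    idx <- (sites$g_start[k] + 1L):sites$g_end[k]
    genome_chars[idx] <- strsplit(sitedna, "")[[1]]
  }
  genome <- stats::setNames(paste(genome_chars, collapse = ""), config$chrom)

  ## reads: full-coverage piles over each site, plus uniform background
  read_rows <- list()
  for (k in seq_len(nrow(sites))) {
    d <- sites$depth[k]
    lo <- max(0L, sites$g_end[k] - rl)
    hi <- min(config$genome_length - rl, sites$g_start[k])
    starts <- sample(seq.int(lo, hi), d, replace = TRUE)
    read_rows[[length(read_rows) + 1L]] <- data.frame(
      chrom = config$chrom, start = starts, end = starts + rl,
      strand = sites$strand[k], origin = sites$site_id[k],
      stringsAsFactors = FALSE)
  }
  if (config$n_background_reads > 0) {
    starts <- sample.int(config$genome_length - rl,
                         config$n_background_reads, replace = TRUE) - 1L
    read_rows[[length(read_rows) + 1L]] <- data.frame(
      chrom = config$chrom, start = starts, end = starts + rl,
      strand = sample(c("+", "-"), config$n_background_reads, replace = TRUE),
      origin = "background", stringsAsFactors = FALSE)
  }
  reads <- if (length(read_rows)) do.call(rbind, read_rows) else
    cbind(empty_reads()[, c("chrom", "start", "end", "strand")],
          data.frame(origin = character()))
  if (nrow(reads)) {
    sources <- paste0("Ago", seq_len(config$n_sources))
    reads$ago_source <- sample(sources, nrow(reads), replace = TRUE)
    reads$read_id <- sprintf("r%06d", seq_len(nrow(reads)))
    gseq <- genome[[1]]
    raw <- substring(gseq, reads$start + 1L, reads$end)
    raw[reads$strand == "-"] <- revcomp(raw[reads$strand == "-"], "dna")
    if (config$tc_conversion_rate > 0) {
      raw <- vapply(raw, function(s) {
        ch <- strsplit(s, "")[[1]]
        conv <- ch == "T" & stats::runif(length(ch)) < config$tc_conversion_rate
        ch[conv] <- "C"
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    reads$seq <- raw
    reads <- reads[, c("chrom", "start", "end", "strand", "read_id",
                       "ago_source", "seq", "origin")]
  } else {
    reads <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        read_id = character(), ago_source = character(),
                        seq = character(), origin = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(reads) <- NULL

  ## validated miRNA-mRNA pairs
  mrna_ids <- unique(transcripts$transcript_id[
    transcripts$biotype == "protein_coding"])
  validated <- data.frame(mirna_id = character(),
                          transcript_id = character(),
                          stringsAsFactors = FALSE)
  if (config$n_validated > 0 && length(mrna_ids) && length(mirnas)) {
    n <- min(config$n_validated, length(mrna_ids) * length(mirnas))
    all_pairs <- expand.grid(mirna_id = names(mirnas),
                             transcript_id = mrna_ids,
                             stringsAsFactors = FALSE)
    validated <- all_pairs[sample.int(nrow(all_pairs), n), , drop = FALSE]
    validated <- validated[order(validated$mirna_id,
                                 validated$transcript_id), , drop = FALSE]
    rownames(validated) <- NULL
  }

  structure(list(genome = genome, transcripts = transcripts,
                 mirnas = mirnas, reads = reads, validated = validated,
                 truth = list(sites = sites,
                              n_background = config$n_background_reads),
                 config = config),
            class = "synthetic_bundle")
}

# Planted-site DNA for a miRNA: exact reverse complement, or the reverse
# complement of seed positions 2-8 embedded in random context of the same
# total length.
site_sequence <- function(mirna, site_kind) {
  dna <- normalize_alphabet(mirna, "dna")
  if (site_kind == "full_complement") return(revcomp(dna, "dna"))
  n <- nchar(dna)
  seed_rc <- revcomp(substr(dna, 2, 7 + 1), "dna")  # miRNA positions 2-8
  left <- rand_seq(max(0, n - nchar(seed_rc) - 1))
  paste0(left, seed_rc, rand_seq(1))
}

# Choose transcript, exon and spliced position for every planted site,
# honoring the positional-bias mixture and keeping read envelopes of
# distinct sites disjoint so each pile yields its own cluster.
plant_sites <- function(config, transcripts, mirnas) {
  empty <- data.frame(site_id = character(), mirna_id = character(),
                      transcript_id = character(), exon_index = integer(),
                      tx_start = integer(), tx_end = integer(),
                      g_start = integer(), g_end = integer(),
                      strand = character(), depth = integer(),
                      stringsAsFactors = FALSE)
  if (config$n_planted_sites == 0) return(empty)
  assert_that(length(mirnas) > 0,
              "cannot plant sites without miRNAs")
  assert_that(nrow(transcripts) > 0,
              "cannot plant sites without transcripts")
  tx_ids <- unique(transcripts$transcript_id)
  lens <- spliced_lengths(transcripts)
  margin <- config$read_length
  used <- stats::setNames(vector("list", length(tx_ids)), tx_ids)
  rows <- list()
  for (k in seq_len(config$n_planted_sites)) {
    mir <- sample(names(mirnas), 1)
    len <- nchar(mirnas[[mir]])
    if (len > min(lens)) {
      # only a real constraint if some transcript is shorter than the site
      if (len > max(lens)) {
        stop("infeasible geometry: planted site longer than every transcript",
             call. = FALSE)
      }
    }
    biased <- stats::runif(1) < config$positional_bias
    placed <- FALSE
    for (tid in sample(tx_ids)) {
      tx <- transcripts[transcripts$transcript_id == tid, ]
      tx <- tx[order(tx$start), ]
      L <- lens[[tid]]
      if (len > L) next
      exlens <- tx$end - tx$start
      t_ends <- cumsum(exlens)
      t_starts <- t_ends - exlens
      # feasible spliced start positions: site within one exon, in
      # transcript orientation; exon spliced spans for '-' transcripts are
      # the reversed complement blocks
      spans <- if (tx$strand[1] == "+") {
        cbind(t_starts, t_ends)
      } else {
        cbind(L - t_ends, L - t_starts)[rev(seq_len(nrow(tx))), , drop = FALSE]
      }
      feas <- integer(0)
      for (r in seq_len(nrow(spans))) {
        lo <- spans[r, 1]; hi <- spans[r, 2] - len
        if (hi < lo) next
        feas <- c(feas, seq.int(lo, hi))
      }
      if (biased) {
        # midpoint constrained to the final decile
        feas <- feas[(feas + len / 2) / L >= 0.9]
      }
      if (!is.null(used[[tid]]) && length(used[[tid]])) {
        for (iv in used[[tid]]) {
          feas <- feas[feas + len <= iv[1] - margin | feas >= iv[2] + margin]
        }
      }
      if (!length(feas)) next
      s <- if (length(feas) == 1) feas else sample(feas, 1)
      ts <- s; te <- s + len
      g <- sort(transcript_to_genomic(tx, c(ts, te - 1L)))
      exon_index <- tx$exon_index[g[1] >= tx$start & g[1] < tx$end]
      used[[tid]] <- c(used[[tid]], list(c(ts, te)))
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("site%03d", k), mirna_id = mir,
        transcript_id = tid, exon_index = exon_index,
        tx_start = ts, tx_end = te,
        g_start = g[1], g_end = g[2] + 1L,
        strand = tx$strand[1],
        depth = runif_int(1, config$site_depth),
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("infeasible geometry: no transcript can host another planted site",
           call. = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a synthetic bundle to disk in standard formats
#'
#' Emits `genome.fa`, `transcripts.gtf`, `mirnas.fa`, per-source
#' `reads_<Ago>.bed` and `reads_<Ago>.fa`, `validated.tsv` and a JSON
#' ground-truth manifest `truth.json`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_gtf(bundle$transcripts, file.path(dir, "transcripts.gtf"))
  write_fasta(bundle$mirnas, file.path(dir, "mirnas.fa"))
  sources <- paste0("Ago", seq_len(bundle$config$n_sources))
  for (s in sources) {
    sel <- bundle$reads[bundle$reads$ago_source == s, , drop = FALSE]
    bed <- sel
    bed$name <- sel$read_id
    bed$score <- rep(0L, nrow(sel))
    write_bed(if (nrow(bed)) bed else
      cbind(empty_reads()[, c("chrom", "start", "end", "strand")],
            name = character(), score = integer()),
      file.path(dir, paste0("reads_", s, ".bed")))
    write_fasta(stats::setNames(sel$seq, sel$read_id),
                file.path(dir, paste0("reads_", s, ".fa")))
  }
  utils::write.table(bundle$validated, file.path(dir, "validated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(sites = bundle$truth$sites,
                n_background = bundle$truth$n_background,
                seed = bundle$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Map reads to a genome by exact matching
#'
#' Places every read at every exact-match position on either strand of the
#' genome (a minus-strand placement is an exact match of the read's reverse
#' complement). Reads with no exact match anywhere are dropped; the number
#' dropped is attached as attribute `n_dropped` (PAR-CLIP T-to-C converted
#' reads are lost this way under no-mismatch mapping).
#'
#' @param read_seqs Named character vector of read sequences (DNA, equal
#'   lengths).
#' @param genome Named character vector of chromosome sequences.
#' @param source_label Ago label stamped on the output.
#' @return Mapped-read data.frame with attribute `n_dropped`.
#' @export
map_reads_exact <- function(read_seqs, genome, source_label = "Ago1") {
  out <- empty_reads()
  if (length(read_seqs)) {
    hits <- list()
    fwd <- Biostrings::DNAStringSet(read_seqs)
    rev <- Biostrings::reverseComplement(fwd)
    for (chrom in names(genome)) {
      subject <- Biostrings::DNAString(genome[[chrom]])
      for (strand in c("+", "-")) {
        pd <- Biostrings::PDict(if (strand == "+") fwd else rev)
        m <- Biostrings::matchPDict(pd, subject)
        for (i in seq_along(m)) {
          ir <- m[[i]]
          if (!length(ir)) next
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, start = IRanges::start(ir) - 1L,
            end = IRanges::end(ir), strand = strand,
            read_id = names(read_seqs)[i], ago_source = source_label,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) out <- do.call(rbind, hits)
  }
  out <- order_intervals(out)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(setdiff(names(read_seqs), out$read_id))
  out
}
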