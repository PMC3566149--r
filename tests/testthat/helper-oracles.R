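# Independent brute-force oracles. These deliberately re-derive results by
# the most literal method available (per-base marking, base-set
# intersection, exhaustive recursion, union-find) and share no code with the
# implementation paths they check.

# Per-base cluster-calling oracle: mark every position covered by >= min_depth
# reads, take maximal runs, count per-source overlap support.
oracle_call_clusters <- function(reads, min_depth, sources = NULL) {
  if (is.null(sources)) sources <- sort(unique(reads$ago_source))
  out <- list()
  for (key in sort(unique(paste(reads$chrom, reads$strand)))) {
    g <- reads[paste(reads$chrom, reads$strand) == key, ]
    maxend <- max(g$end)
    cov <- integer(maxend)
    for (r in seq_len(nrow(g))) {
      idx <- (g$start[r] + 1L):g$end[r]
      cov[idx] <- cov[idx] + 1L
    }
    ok <- cov >= min_depth
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths   # 0-based starts
    for (i in which(r$values)) {
      s0 <- starts[i]; e0 <- ends[i]
      sup <- vapply(sources, function(src) {
        sel <- g$ago_source == src
        sum(g$start[sel] < e0 & g$end[sel] > s0)
      }, integer(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = g$chrom[1], start = s0, end = e0, strand = g$strand[1],
        max_depth = max(cov[(s0 + 1L):e0]),
        total_support = sum(sup),
        t(sup), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  df <- do.call(rbind, out)
  names(df)[-(1:6)] <- paste0("support_", sources)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Base-by-base overlap oracle: test every (element, transcript, exon) triple
# by intersecting explicit base sets.
oracle_assign <- function(elements, transcripts, same_strand = TRUE) {
  rows <- list()
  for (e in seq_len(nrow(elements))) {
    el_bases <- seq.int(elements$start[e], elements$end[e] - 1L)
    for (x in seq_len(nrow(transcripts))) {
      ex <- transcripts[x, ]
      if (ex$chrom != elements$chrom[e]) next
      if (same_strand && ex$strand != elements$strand[e]) next
      common <- intersect(el_bases, seq.int(ex$start, ex$end - 1L))
      if (!length(common)) next
      tx <- transcripts[transcripts$transcript_id == ex$transcript_id, ]
      tpos <- sort(genomic_to_transcript(tx, common))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = elements$cluster_id[e],
        transcript_id = ex$transcript_id, exon_index = ex$exon_index,
        tx_start = tpos[1], tx_end = tpos[length(tpos)] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = character(), transcript_id = character(),
                      exon_index = integer(), tx_start = integer(),
                      tx_end = integer()))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$cluster_id, df$transcript_id, df$exon_index), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exhaustive duplex-alignment oracle: top-down recursion over all local
# alignments with affine gap states (memoized for tractability; the pure
# enumeration below cross-checks it on very short inputs).
oracle_duplex_score <- function(mirna, site, params = scoring_params()) {
  a <- rev(strsplit(toupper(mirna), "")[[1]])
  b <- strsplit(toupper(site), "")[[1]]
  n <- length(a); m <- length(b)
  mir_pos <- n - seq_len(n) + 1L
  w <- ifelse(mir_pos >= params$seed_start & mir_pos <= params$seed_end,
              params$seed_scale, 1)
  sc <- function(i, j) {
    pc <- mrenet:::pair_class(a[i], b[j])
    c(params$mismatch, params$wobble, params$match)[pc + 1L] * w[i]
  }
  memo <- new.env()
  # best(i, j, st): best score of an alignment suffix starting at (i, j) in
  # state st (1 = about to emit a column pair, 2 = inside a miRNA-side gap,
  # 3 = inside a target-side gap); the alignment may end at any pair column.
  best <- function(i, j, st) {
    if (i > n || j > m) return(-Inf)
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- -Inf
    if (st == 1L) {
      here <- sc(i, j)
      v <- max(v, here,                                    # end here
               here + best(i + 1L, j + 1L, 1L),            # next pair
               here + params$gap_open + best(i + 2L, j + 1L, 2L),
               here + params$gap_open + best(i + 1L, j + 2L, 3L))
    } else if (st == 2L) {                                 # gap in target
      v <- max(best(i, j, 1L),
               params$gap_extend + best(i + 1L, j, 2L))
    } else {
      v <- max(best(i, j, 1L),
               params$gap_extend + best(i, j + 1L, 3L))
    }
    memo[[key]] <- v
    v
  }
  out <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    out <- max(out, best(i, j, 1L))
  }
  out
}

# Pure enumeration over all monotone sets of aligned column pairs (gaps fill
# the space between consecutive pairs); exponential, for tiny inputs only.
oracle_duplex_enumerate <- function(mirna, site, params = scoring_params()) {
  a <- rev(strsplit(toupper(mirna), "")[[1]])
  b <- strsplit(toupper(site), "")[[1]]
  n <- length(a); m <- length(b)
  mir_pos <- n - seq_len(n) + 1L
  w <- ifelse(mir_pos >= params$seed_start & mir_pos <= params$seed_end,
              params$seed_scale, 1)
  colscore <- function(i, j) {
    pc <- mrenet:::pair_class(a[i], b[j])
    c(params$mismatch, params$wobble, params$match)[pc + 1L] * w[i]
  }
  gapcost <- function(len) {
    if (len == 0) 0 else params$gap_open + params$gap_extend * (len - 1)
  }
  best <- 0
  walk <- function(i, j, score) {
    # a column pair at (i, j) has been emitted; alignment may stop here
    best <<- max(best, score)
    if (i < n && j < m) {
      for (ni in (i + 1L):n) for (nj in (j + 1L):m) {
        da <- ni - i - 1L; db <- nj - j - 1L
        if (da > 0 && db > 0) next   # adjacent gaps on both sides never help
        walk(ni, nj, score + gapcost(da) + gapcost(db) + colscore(ni, nj))
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) walk(i, j, colscore(i, j))
  best
}

# Linear-gap Smith-Waterman score oracle for the ortholog aligner.
oracle_sw_score <- function(q, s, match = 1, mismatch = -1, gap = -2) {
  qa <- strsplit(toupper(q), "")[[1]]
  sa <- strsplit(toupper(s), "")[[1]]
  n <- length(qa); m <- length(sa)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d <- if (qa[i] == sa[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + d, H[i, j + 1] + gap,
                           H[i + 1, j] + gap)
  }
  max(H)
}

# Union-find connected-components oracle.
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$source[k]); rb <- find(edges$target[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  list(n_components = length(unique(roots)),
       sizes = sort(as.integer(table(roots))))
}
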