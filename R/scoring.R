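#' Duplex-scoring parameters
#'
#' Defaults follow the published miRanda scoring scheme: Watson-Crick match
#' +5, G:U wobble +1, mismatch -3, affine gaps -9 to open / -4 to extend
#' (a gap of length L costs open + (L-1) x extend), with pair scores at
#' miRNA seed positions 2-8 (1-based from the miRNA 5' end) multiplied by
#' `seed_scale`. The reporting thresholds are an alignment score of at least
#' 160 together with a duplex hybridization energy of at most -20 kcal/mol.
#'
#' @param match,wobble,mismatch Per-column pair scores.
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @param seed_start,seed_end 1-based seed range on the miRNA.
#' @param seed_scale Multiplier applied to pair scores at seed positions.
#' @param score_min Minimum alignment score for a reported hit.
#' @param energy_max Maximum duplex free energy (kcal/mol) for a reported hit.
#' @param site_flank Nucleotides of transcript context added on each side of
#'   an element when extracting candidate sites.
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(match = 5, wobble = 1, mismatch = -3,
                           gap_open = -9, gap_extend = -4,
                           seed_start = 2L, seed_end = 8L, seed_scale = 4,
                           score_min = 160, energy_max = -20,
                           site_flank = 15L) {
  assert_that(score_min > 0, "score_min must be positive")
  assert_that(energy_max < 0, "energy_max must be negative")
  assert_that(seed_start >= 1L && seed_end >= seed_start,
              "seed positions must form a 1-based contiguous range")
  assert_that(site_flank >= 0L, "site_flank must be >= 0")
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end), seed_scale = seed_scale,
                 score_min = score_min, energy_max = energy_max,
                 site_flank = as.integer(site_flank)),
            class = "scoring_params")
}

# Pair class of a miRNA base vs a target base (both RNA): 2 = Watson-Crick,
# 1 = G:U wobble, 0 = mismatch.
pair_class <- function(m, t) {
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, 2L, ifelse(gu, 1L, 0L))
}

#' Align a miRNA against a candidate site
#'
#' Local (Smith-Waterman) alignment of the miRNA, antiparallel (3'->5'),
#' against the target site (5'->3') under the miRanda-style pair scores with
#' affine gaps and seed weighting. Ties are broken deterministically: maximal
#' score, then shortest alignment, then smallest target start. If no positive-
#' scoring local alignment exists the score is 0 and the alignment is empty.
#'
#' @param mirna miRNA sequence, RNA alphabet, 5'->3'.
#' @param site Target site sequence, RNA alphabet, 5'->3'.
#' @param params A [scoring_params()] list.
#' @return A `duplex_alignment` list: `score`; `mirna_aln` (gapped miRNA,
#'   written 3'->5'), `pair_line` (`|` Watson-Crick, `:` wobble, space
#'   otherwise), `target_aln` (gapped target, 5'->3'); `target_start`,
#'   `target_end` (0-based half-open on the site); `mirna_start`,
#'   `mirna_end` (0-based half-open on the miRNA, 5'->3').
#' @export
align_duplex <- function(mirna, site, params = scoring_params()) {
  assert_that(nchar(mirna) >= 6L && nchar(site) >= 6L,
              "sequences must be at least 6 nt")
  a <- rev(strsplit(toupper(mirna), "")[[1]])   # miRNA 3'->5'
  b <- strsplit(toupper(site), "")[[1]]          # target 5'->3'
  n <- length(a); m <- length(b)
  # per-position weight: a[i] is miRNA position n - i + 1 (1-based from 5')
  mir_pos <- n - seq_len(n) + 1L
  w <- ifelse(mir_pos >= params$seed_start & mir_pos <= params$seed_end,
              params$seed_scale, 1)
  base_score <- c(params$mismatch, params$wobble, params$match)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L); M[1, ] <- M[, 1] <- NEG
  Ix <- matrix(NEG, n + 1L, m + 1L)   # miRNA base vs gap in target
  Iy <- matrix(NEG, n + 1L, m + 1L)   # gap in miRNA vs target base
  ptrM <- matrix(0L, n + 1L, m + 1L)  # 0 fresh, 1 M, 2 Ix, 3 Iy
  ptrX <- matrix(0L, n + 1L, m + 1L)  # 1 from M, 2 from Ix
  ptrY <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    pc <- pair_class(a[i], b)
    s_row <- base_score[pc + 1L] * w[i]
    for (j in seq_len(m)) {
      prev <- c(0,
                M[i, j], Ix[i, j], Iy[i, j])
      k <- which.max(prev)  # prefers fresh start, then M, then Ix, then Iy
      M[i + 1L, j + 1L] <- prev[k] + s_row[j]
      ptrM[i + 1L, j + 1L] <- k - 1L
      fromM <- M[i, j + 1L] + params$gap_open
      fromX <- Ix[i, j + 1L] + params$gap_extend
      if (fromM >= fromX) {
        Ix[i + 1L, j + 1L] <- fromM; ptrX[i + 1L, j + 1L] <- 1L
      } else {
        Ix[i + 1L, j + 1L] <- fromX; ptrX[i + 1L, j + 1L] <- 2L
      }
      fromM <- M[i + 1L, j] + params$gap_open
      fromY <- Iy[i + 1L, j] + params$gap_extend
      if (fromM >= fromY) {
        Iy[i + 1L, j + 1L] <- fromM; ptrY[i + 1L, j + 1L] <- 1L
      } else {
        Iy[i + 1L, j + 1L] <- fromY; ptrY[i + 1L, j + 1L] <- 2L
      }
    }
  }
  best <- max(M)
  if (best <= 0) {
    return(structure(list(score = 0, mirna_aln = "", pair_line = "",
                          target_aln = "", target_start = 0L,
                          target_end = 0L, mirna_start = 0L,
                          mirna_end = 0L), class = "duplex_alignment"))
  }
  cand <- which(M == best, arr.ind = TRUE)
  tracebacks <- lapply(seq_len(nrow(cand)), function(r) {
    traceback_duplex(cand[r, 1], cand[r, 2], a, b, M, Ix, Iy,
                     ptrM, ptrX, ptrY)
  })
  lens <- vapply(tracebacks, function(t) nchar(t$mirna_aln), integer(1))
  starts <- vapply(tracebacks, function(t) t$target_start, integer(1))
  pick <- order(lens, starts)[1]
  tb <- tracebacks[[pick]]
  tb$score <- best
  structure(tb, class = "duplex_alignment")
}

traceback_duplex <- function(ei, ej, a, b, M, Ix, Iy, ptrM, ptrX, ptrY) {
  i <- ei; j <- ej; state <- 1L  # 1 M, 2 Ix, 3 Iy; traceback ends in M
  top <- character(); mid <- character(); bot <- character()
  repeat {
    if (state == 1L) {
      pc <- pair_class(a[i - 1L], b[j - 1L])
      top <- c(a[i - 1L], top)
      mid <- c(c(" ", ":", "|")[pc + 1L], mid)
      bot <- c(b[j - 1L], bot)
      nxt <- ptrM[i, j]
      i <- i - 1L; j <- j - 1L
      if (nxt == 0L) break
      state <- nxt
    } else if (state == 2L) {
      top <- c(a[i - 1L], top); mid <- c(" ", mid); bot <- c("-", bot)
      nxt <- ptrX[i, j]
      i <- i - 1L
      state <- if (nxt == 1L) 1L else 2L
    } else {
      top <- c("-", top); mid <- c(" ", mid); bot <- c(b[j - 1L], bot)
      nxt <- ptrY[i, j]
      j <- j - 1L
      state <- if (nxt == 1L) 1L else 3L
    }
  }
  n <- length(a)
  # i, j are now the 1-based indices of the first aligned column in a
  # (miRNA 3'->5') and b; the 0-based starts are i - 1 and j - 1
  list(mirna_aln = paste(top, collapse = ""),
       pair_line = paste(mid, collapse = ""),
       target_aln = paste(bot, collapse = ""),
       target_start = as.integer(j - 1L), target_end = as.integer(ej - 1L),
       mirna_start = as.integer(n - (ei - 1L)),
       mirna_end = as.integer(n - i + 1L))
}

#' Extract a candidate target site around an annotated element
#'
#' Takes the element's spliced-coordinate span on the transcript plus
#' `flank` nucleotides of context on each side, clipped to the transcript
#' bounds.
#'
#' @param tx_seq Spliced transcript sequence (character scalar).
#' @param annotation One row of [assign_clusters()] output.
#' @param flank Nucleotides of flank on each side.
#' @return List with `id`, `seq`, `site_start`, `site_end` (0-based half-open
#'   on the transcript).
#' @export
extract_site <- function(tx_seq, annotation, flank = 15L) {
  len <- nchar(tx_seq)
  assert_that(annotation$tx_start >= 0L && annotation$tx_end <= len &&
                annotation$tx_start < annotation$tx_end,
              sprintf("annotation span [%d,%d) outside sequence of length %d",
                      annotation$tx_start, annotation$tx_end, len))
  s <- max(0L, annotation$tx_start - flank)
  e <- min(len, annotation$tx_end + flank)
  list(id = paste(annotation$cluster_id, annotation$transcript_id, sep = "|"),
       seq = substr(tx_seq, s + 1L, e),
       site_start = as.integer(s), site_end = as.integer(e))
}

#' Extract all candidate sites for an annotation table
#'
#' @param annotations Output of [assign_clusters()].
#' @param tx_seqs Named vector of spliced transcript sequences (DNA or RNA).
#' @param flank Flank in nt (see [extract_site()]).
#' @return Data.frame with `site_id`, `cluster_id`, `transcript_id`,
#'   `biotype_class`, `site_start`, `site_end`, `seq` (RNA alphabet).
#' @export
extract_sites <- function(annotations, tx_seqs, flank = 15L) {
  rows <- lapply(seq_len(nrow(annotations)), function(k) {
    ann <- annotations[k, ]
    if (!ann$transcript_id %in% names(tx_seqs)) {
      stop_located("site extraction error", ann$transcript_id,
                   "no sequence supplied for annotated transcript")
    }
    site <- extract_site(tx_seqs[[ann$transcript_id]], ann, flank)
    data.frame(site_id = paste0(site$id, "@", site$site_start),
               cluster_id = ann$cluster_id,
               transcript_id = ann$transcript_id,
               biotype_class = ann$biotype_class,
               site_start = site$site_start, site_end = site$site_end,
               seq = normalize_alphabet(site$seq, "rna"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), cluster_id = character(),
               transcript_id = character(), biotype_class = character(),
               site_start = integer(), site_end = integer(),
               seq = character(), stringsAsFactors = FALSE)
  unique(out)
}

#' Predict cognate miRNAs for candidate sites
#'
#' Scores every (miRNA, site) pair with [align_duplex()] and
#' [duplex_energy()] and reports the pairs passing both thresholds
#' (score >= `score_min` and energy <= `energy_max`); one best hit per
#' (miRNA, site).
#'
#' @param mirnas Named character vector of mature miRNA sequences (RNA).
#' @param sites Site table from [extract_sites()].
#' @param params A [scoring_params()] list.
#' @param energy_table A [nn_energy_table()].
#' @return Data.frame sorted by (cluster_id, mirna_id) with columns
#'   `mirna_id`, `cluster_id`, `transcript_id`, `site_id`, `biotype_class`,
#'   `tx_start`, `tx_end` (aligned span on the transcript), `score`,
#'   `energy`, `mirna_aln`, `pair_line`, `target_aln`.
#' @export
predict_targets <- function(mirnas, sites, params = scoring_params(),
                            energy_table = nn_energy_table()) {
  empty <- data.frame(mirna_id = character(), cluster_id = character(),
                      transcript_id = character(), site_id = character(),
                      biotype_class = character(), tx_start = integer(),
                      tx_end = integer(), score = numeric(),
                      energy = numeric(), mirna_aln = character(),
                      pair_line = character(), target_aln = character(),
                      stringsAsFactors = FALSE)
  if (!length(mirnas) || !nrow(sites)) return(empty)
  rows <- list()
  for (mi in seq_along(mirnas)) {
    mseq <- normalize_alphabet(mirnas[[mi]], "rna")
    for (si in seq_len(nrow(sites))) {
      aln <- align_duplex(mseq, sites$seq[si], params)
      if (aln$score < params$score_min) next
      en <- duplex_energy(aln, energy_table)
      if (en > params$energy_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = names(mirnas)[mi],
        cluster_id = sites$cluster_id[si],
        transcript_id = sites$transcript_id[si],
        site_id = sites$site_id[si],
        biotype_class = sites$biotype_class[si],
        tx_start = sites$site_start[si] + aln$target_start,
        tx_end = sites$site_start[si] + aln$target_end,
        score = aln$score, energy = en,
        mirna_aln = aln$mirna_aln, pair_line = aln$pair_line,
        target_aln = aln$target_aln, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_id, out$mirna_id, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a duplex alignment for display
#'
#' @param x A `duplex_alignment`.
#' @param ... Unused.
#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("score %.1f\n", x$score))
  cat("miRNA  3' ", x$mirna_aln, " 5'\n", sep = "")
  cat("          ", x$pair_line, "\n", sep = "")
  cat("target 5' ", x$target_aln, " 3'\n", sep = "")
  invisible(x)
}
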