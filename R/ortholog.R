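#' Best local alignment of a query lncRNA against target sequences
#'
#' Smith-Waterman local alignment over both strands of every target record
#' (match +1, mismatch -1, gap -2 per gapped position), standing in for a
#' BLAT search at desk scale. Ties are broken deterministically by
#' (target_id, start, strand).
#'
#' @param query Query sequence (DNA, character scalar).
#' @param targets Named character vector of target sequences (DNA).
#' @param match,mismatch Per-column scores.
#' @param gap Per-gapped-position penalty (linear).
#' @param min_score Reporting floor; if no alignment reaches it, `NULL` is
#'   returned.
#' @return A list (`ortholog_alignment`): `target_id`, `strand`,
#'   `target_start`, `target_end` (0-based half-open on the forward target),
#'   `query_start`, `query_end`, `score`, `n_match`, `n_columns` (alignment
#'   columns including gaps), `aligned_query_length`; or `NULL` when nothing
#'   reaches `min_score`.
#' @export
local_align_genome <- function(query, targets, match = 1, mismatch = -1,
                               gap = -2, min_score = 20) {
  assert_that(is.character(query) && length(query) == 1 && nzchar(query),
              "query must be a non-empty sequence")
  assert_that(length(targets) > 0 && all(nzchar(targets)),
              "targets must be non-empty sequences")
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  best <- NULL
  for (tid in names(targets)) {
    tlen <- nchar(targets[[tid]])
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") targets[[tid]] else
        revcomp(targets[[tid]], "dna")
      pa <- Biostrings::pairwiseAlignment(
        pattern = query, subject = subject, type = "local",
        substitutionMatrix = submat, gapOpening = 0, gapExtension = -gap)
      sc <- Biostrings::score(pa)
      if (sc < min_score) next
      srng <- Biostrings::subject(pa)
      prng <- Biostrings::pattern(pa)
      s1 <- IRanges::start(srng) - 1L   # 0-based on aligned strand
      e1 <- IRanges::end(srng)
      if (strand == "-") {
        tmp <- tlen - e1
        e1 <- tlen - s1
        s1 <- tmp
      }
      cand <- list(target_id = tid, strand = strand,
                   target_start = as.integer(s1), target_end = as.integer(e1),
                   query_start = as.integer(IRanges::start(prng) - 1L),
                   query_end = as.integer(IRanges::end(prng)),
                   score = sc,
                   n_match = Biostrings::nmatch(pa),
                   n_columns = IRanges::nchar(pa),
                   aligned_query_length =
                     as.integer(IRanges::end(prng) -
                                  IRanges::start(prng) + 1L))
      if (is.null(best) || sc > best$score ||
          (sc == best$score &&
             (cand$target_id < best$target_id ||
                (cand$target_id == best$target_id &&
                   (cand$target_start < best$target_start ||
                      (cand$target_start == best$target_start &&
                         cand$strand < best$strand)))))) {
        best <- cand
      }
    }
  }
  if (!is.null(best)) class(best) <- "ortholog_alignment"
  best
}

#' Identity and query-coverage percentages for an alignment
#'
#' Identity is matches over aligned columns (gaps included) x 100; the
#' alignment percentage is the aligned query length over the full query
#' length x 100 (query coverage). Hits below `identity_min` are filtered
#' (a 0-row data.frame is returned).
#'
#' @param alignment An `ortholog_alignment` from [local_align_genome()].
#' @param query_id Query identifier to report.
#' @param query_length Full query length (nt).
#' @param identity_min Minimum identity percentage for a reported hit.
#' @return A data.frame with 0 or 1 rows: `query_id`, `target_id`, `start`,
#'   `end`, `strand`, `identity_pct`, `alignment_pct`.
#' @export
score_hit <- function(alignment, query_id, query_length, identity_min = 90) {
  assert_that(!is.null(alignment) && alignment$n_columns > 0,
              "alignment is empty")
  identity_pct <- 100 * alignment$n_match / alignment$n_columns
  alignment_pct <- 100 * alignment$aligned_query_length / query_length
  out <- data.frame(query_id = query_id, target_id = alignment$target_id,
                    start = alignment$target_start,
                    end = alignment$target_end, strand = alignment$strand,
                    identity_pct = identity_pct,
                    alignment_pct = alignment_pct,
                    stringsAsFactors = FALSE)
  out[out$identity_pct >= identity_min, , drop = FALSE]
}

#' Map query lncRNAs onto target sequences
#'
#' Runs [local_align_genome()] and [score_hit()] for every query and keeps
#' hits passing the identity threshold. Hits are labelled putative: no
#' expression-evidence confirmation is attempted.
#'
#' @param queries Named character vector of query lncRNA sequences (DNA).
#' @param targets Named character vector of target sequences (DNA).
#' @param identity_min Minimum identity percentage.
#' @param ... Passed to [local_align_genome()].
#' @return Data.frame of hits (possibly 0 rows), one best hit per query,
#'   columns as in [score_hit()].
#' @export
map_orthologs <- function(queries, targets, identity_min = 90, ...) {
  rows <- lapply(names(queries), function(qid) {
    aln <- local_align_genome(queries[[qid]], targets, ...)
    if (is.null(aln)) return(NULL)
    score_hit(aln, qid, nchar(queries[[qid]]), identity_min)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(query_id = character(), target_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), identity_pct = numeric(),
                      alignment_pct = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
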