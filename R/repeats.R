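blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

aa_codes <- function(residues, letters) {
  m <- match(strsplit(residues, "")[[1]], letters)
  if (anyNA(m)) stop("residue outside the scoring alphabet")
  m - 1L
}

# Best-scoring contiguous sub-path of an alignment whose projected
# intervals do not overlap (max residue index on the first side strictly
# below the min index on the second). Used when the optimal local
# self-alignment extends marginally past the repeat unit so that its raw
# spans overlap. Window scores re-apply the affine gap cost (open + ext*L
# per maximal gap run, clipped runs pay the opening again); ties break by
# longer window, then smaller start. Returns NULL when no window contains
# residues on both sides.
trim_to_nonoverlap <- function(ai, aj, res, sub, gap_open, gap_ext) {
  P <- length(ai)
  best <- NULL
  for (u in seq_len(P)) {
    score <- 0
    prev <- ""
    maxi <- -Inf
    firstj <- Inf
    for (v in u:P) {
      type <- if (aj[v] == 0) "Ix" else if (ai[v] == 0) "Iy" else "M"
      if (type == "M") {
        score <- score + sub[res[ai[v]], res[aj[v]]]
        maxi <- max(maxi, ai[v])
        firstj <- min(firstj, aj[v])
      } else if (type == "Ix") {
        score <- score - if (prev == "Ix") gap_ext else gap_open + gap_ext
        maxi <- max(maxi, ai[v])
      } else {
        score <- score - if (prev == "Iy") gap_ext else gap_open + gap_ext
        firstj <- min(firstj, aj[v])
      }
      prev <- type
      if (is.finite(maxi) && is.finite(firstj) && maxi >= firstj) break
      if (is.finite(maxi) && is.finite(firstj)) {
        len <- v - u + 1L
        if (is.null(best) || score > best$score ||
            (score == best$score && (len > best$len ||
             (len == best$len && u < best$u)))) {
          best <- list(score = score, u = u, v = v, len = len)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  idx <- best$u:best$v
  list(ai = ai[idx], aj = aj[idx], score = best$score)
}

#' Detect internal tandem repeats by local self-alignment
#'
#' Finds homologous intra-sequence regions by computing the optimal local
#' alignment of the sequence against itself with the near-diagonal band
#' `|i - j| < min_unit_len` excluded (so the trivial self-match is
#' unreachable), under BLOSUM62 with affine gaps. If the best off-diagonal
#' alignment has identity at least `min_identity` and both projected
#' intervals are at least `min_unit_len` long and non-overlapping, a call is
#' emitted, both intervals are masked, and the search iterates (up to
#' `max_rounds` calls). When the optimal alignment's raw spans overlap
#' marginally (it extended past the repeat unit), it is first trimmed to its
#' best-scoring non-overlapping sub-path and the criteria are applied to the
#' trimmed alignment, so emitted intervals never overlap. Identity is the
#' percentage of identical columns over all alignment columns, gap columns
#' included. The first best alignment that still fails a criterion ends the
#' search.
#'
#' @param seq A [seq_record()].
#' @param min_identity Minimum percent identity of the repeat alignment
#'   (default 40).
#' @param min_unit_len Minimum repeat-unit length in residues, also the
#'   excluded band half-width (default 20; must be >= 8).
#' @param max_rounds Maximum number of calls (default 3).
#' @param gap_open,gap_ext Affine gap penalties; a gap of length L costs
#'   `gap_open + gap_ext * L` (defaults 11 and 1).
#' @return Data frame of calls: `parent_id`, `start_a`, `end_a`, `start_b`,
#'   `end_b`, `identity`, `score`. Zero rows when nothing qualifies.
#' @export
detect_internal_repeats <- function(seq, min_identity = 40, min_unit_len = 20L,
                                    max_rounds = 3L, gap_open = 11,
                                    gap_ext = 1) {
  stopifnot(inherits(seq, "seq_record"), min_unit_len >= 8)
  sub <- blosum62_matrix()
  letters <- rownames(sub)
  res <- strsplit(seq$residues, "")[[1]]
  codes <- aa_codes(seq$residues, letters)
  n <- length(codes)
  mask <- rep(FALSE, n)
  empty <- data.frame(parent_id = character(), start_a = integer(),
                      end_a = integer(), start_b = integer(),
                      end_b = integer(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < 2 * min_unit_len) return(empty)
  calls <- list()
  for (round in seq_len(max_rounds)) {
    al <- self_align_cpp(codes, sub, as.integer(min_unit_len),
                         gap_open, gap_ext, mask)
    if (al$score <= 0 || length(al$ai) == 0) break
    ai <- al$ai
    aj <- al$aj
    score <- al$score
    if (max(ai) >= min(aj[aj > 0])) {
      tw <- trim_to_nonoverlap(ai, aj, res, sub, gap_open, gap_ext)
      if (is.null(tw) || tw$score <= 0) break
      ai <- tw$ai
      aj <- tw$aj
      score <- tw$score
    }
    both <- ai > 0 & aj > 0
    ident <- 100 * sum(both & res[pmax(ai, 1)] == res[pmax(aj, 1)]) /
      length(ai)
    span_a <- range(ai[ai > 0])
    span_b <- range(aj[aj > 0])
    len_a <- span_a[2] - span_a[1] + 1L
    len_b <- span_b[2] - span_b[1] + 1L
    if (ident < min_identity || len_a < min_unit_len ||
        len_b < min_unit_len || span_a[2] >= span_b[1]) {
      break
    }
    calls[[length(calls) + 1L]] <- data.frame(
      parent_id = seq$id,
      start_a = span_a[1], end_a = span_a[2],
      start_b = span_b[1], end_b = span_b[2],
      identity = ident, score = score, stringsAsFactors = FALSE)
    mask[span_a[1]:span_a[2]] <- TRUE
    mask[span_b[1]:span_b[2]] <- TRUE
  }
  if (length(calls) == 0) return(empty)
  do.call(rbind, calls)
}
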