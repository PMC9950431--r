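pairwise_identity <- function(a, b, gap_open = 11, gap_ext = 1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_ext, type = "global")
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

#' Greedy redundancy clustering of sequence records
#'
#' Removes near-duplicate sequences before alignment and phylogeny. Records
#' are processed in a deterministic order (decreasing length, ties broken by
#' lexicographic id); each record joins the first existing cluster whose
#' representative it matches at identity >= `threshold`, otherwise it founds
#' a new cluster. Identity is the number of identical aligned positions of a
#' global BLOSUM62 alignment divided by the length of the shorter sequence
#' (the CD-HIT convention), so representatives are never shorter than their
#' members and output is invariant to input order.
#'
#' @param records List of [seq_record()] objects.
#' @param threshold Identity fraction in (0, 1]; default 0.99.
#' @return Data frame with columns `representative`, `member`, `identity`
#'   (identity of each member to its representative; 1 for the
#'   representative itself).
#' @export
greedy_cluster <- function(records, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  check_unique_ids(records)
  if (length(records) == 0) {
    return(data.frame(representative = character(), member = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  ids <- record_ids(records)
  lens <- record_lengths(records)
  ord <- order(-lens, ids)
  reps <- integer(0) # indices into records
  out <- list()
  for (k in ord) {
    placed <- FALSE
    for (r in reps) {
      idy <- pairwise_identity(records[[r]]$residues, records[[k]]$residues)
      if (idy >= threshold) {
        out[[length(out) + 1L]] <- data.frame(
          representative = ids[r], member = ids[k], identity = idy,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, k)
      out[[length(out) + 1L]] <- data.frame(
        representative = ids[k], member = ids[k], identity = 1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Representatives of a clustering
#'
#' @param records The records that were clustered.
#' @param clusters Data frame from [greedy_cluster()].
#' @return List of the representative [seq_record()]s, in clustering order.
#' @export
cluster_representatives <- function(records, clusters) {
  ids <- record_ids(records)
  reps <- unique(clusters$representative)
  records[match(reps, ids)]
}
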