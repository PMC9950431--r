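cys_positions_of <- function(residues) {
  which(strsplit(residues, "")[[1]] == "C")
}

window_matches <- function(cys, start_idx, pattern) {
  idx <- start_idx + seq_len(pattern$n_cys) - 1L
  spacings <- diff(cys[idx]) - 1L
  all(spacings >= pattern$loop_bounds[, 1] &
      spacings <= pattern$loop_bounds[, 2])
}

#' Scan a sequence for ICK domains by cysteine spacing
#'
#' Walks the sequence's cysteines left to right and tests every window of
#' `n_cys` consecutive cysteines against the pattern's loop bounds.
#' Overlapping candidate windows are resolved greedily leftmost-first: once
#' a window is accepted, scanning resumes after its last cysteine, so hits
#' never overlap. When several patterns are supplied they are tried in the
#' given order at each candidate start.
#'
#' @param seq A [seq_record()].
#' @param patterns A single [ick_pattern()] or a list of them
#'   (default: the packaged 3-DS pattern).
#' @return A data frame of domain hits with columns `parent_id`, `start`,
#'   `end` (positions of the bounding cysteines, 1-based inclusive),
#'   `ds_class`, and `cys_positions` (semicolon-joined). Zero rows when
#'   nothing matches.
#' @export
scan_ick <- function(seq, patterns = ick_pattern("3DS")) {
  stopifnot(inherits(seq, "seq_record"))
  if (inherits(patterns, "ick_pattern")) patterns <- list(patterns)
  stopifnot(all(vapply(patterns, inherits, logical(1), "ick_pattern")))
  cys <- cys_positions_of(seq$residues)
  hits <- list()
  i <- 1L
  while (i <= length(cys)) {
    matched <- FALSE
    for (p in patterns) {
      if (i + p$n_cys - 1L > length(cys)) next
      if (window_matches(cys, i, p)) {
        idx <- i + seq_len(p$n_cys) - 1L
        hits[[length(hits) + 1L]] <- data.frame(
          parent_id = seq$id,
          start = cys[idx[1]],
          end = cys[idx[length(idx)]],
          ds_class = p$ds_class,
          cys_positions = paste(cys[idx], collapse = ";"),
          stringsAsFactors = FALSE)
        i <- i + p$n_cys # resume after the accepted window
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(hits) == 0) {
    return(data.frame(parent_id = character(), start = integer(),
                      end = integer(), ds_class = character(),
                      cys_positions = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

hit_cys <- function(hit_row) {
  as.integer(strsplit(hit_row$cys_positions, ";", fixed = TRUE)[[1]])
}

#' Split a multi-domain sequence into per-domain records
#'
#' Emits one record per domain hit, spanning its bounding cysteines
#' inclusive, plus a linker report for every adjacent hit pair. The linker is
#' the stretch strictly between the last cysteine of the upstream domain and
#' the first cysteine of the downstream domain. Flanking N-/C-terminal tails
#' are reported in each record's description, not in the domain residues.
#'
#' @param seq A [seq_record()].
#' @param hits Data frame from [scan_ick()] for this sequence (non-overlapping,
#'   sorted by `start`).
#' @return List with `domains` (list of [seq_record()], ids `parent|D1`,
#'   `parent|D2`, ...) and `linkers` (data frame: `upstream`, `downstream`,
#'   `length`).
#' @export
split_domains <- function(seq, hits) {
  stopifnot(inherits(seq, "seq_record"), is.data.frame(hits))
  if (nrow(hits) == 0) {
    return(list(domains = list(),
                linkers = data.frame(upstream = character(),
                                     downstream = character(),
                                     length = integer(),
                                     stringsAsFactors = FALSE)))
  }
  if (any(hits$parent_id != seq$id)) stop("hits do not belong to ", seq$id)
  hits <- hits[order(hits$start), , drop = FALSE]
  if (any(utils::head(hits$end, -1) >= hits$start[-1])) {
    stop("overlapping domain hits for ", seq$id)
  }
  n <- nchar(seq$residues)
  domains <- vector("list", nrow(hits))
  for (k in seq_len(nrow(hits))) {
    ntail <- if (k == 1) hits$start[1] - 1L else NA_integer_
    ctail <- if (k == nrow(hits)) n - hits$end[k] else NA_integer_
    desc <- sprintf("%s domain %d/%d (%d..%d of %s)%s%s",
                    hits$ds_class[k], k, nrow(hits),
                    hits$start[k], hits$end[k], seq$id,
                    if (!is.na(ntail)) sprintf("; N-tail %d aa", ntail) else "",
                    if (!is.na(ctail)) sprintf("; C-tail %d aa", ctail) else "")
    domains[[k]] <- seq_record(
      sprintf("%s|D%d", seq$id, k),
      substr(seq$residues, hits$start[k], hits$end[k]),
      description = desc, source = seq$source)
  }
  linkers <- data.frame(upstream = character(), downstream = character(),
                        length = integer(), stringsAsFactors = FALSE)
  if (nrow(hits) >= 2) {
    linkers <- data.frame(
      upstream = sprintf("%s|D%d", seq$id, seq_len(nrow(hits) - 1L)),
      downstream = sprintf("%s|D%d", seq$id, 2L:nrow(hits)),
      length = hits$start[-1] - utils::head(hits$end, -1) - 1L,
      stringsAsFactors = FALSE)
  }
  list(domains = domains, linkers = linkers)
}

#' Predict knottin disulfide connectivity for a domain hit
#'
#' Applies the knottin pairing rule to the sorted cysteines of one domain:
#' for the three-disulfide form, C1-C4, C2-C5, C3-C6; for the four-disulfide
#' form, the same core (C1-C4, C2-C5, C3-C8) plus the extra loop-four pair
#' C6-C7.
#'
#' @param hit One row of a [scan_ick()] data frame (or a data frame with one
#'   row).
#' @return Data frame with columns `pos_a`, `pos_b`, `rank`.
#' @export
predict_connectivity <- function(hit) {
  stopifnot(is.data.frame(hit), nrow(hit) == 1)
  cys <- sort(hit_cys(hit))
  n <- length(cys)
  if (n == 6L) {
    pairs <- rbind(c(1, 4), c(2, 5), c(3, 6))
  } else if (n == 8L) {
    pairs <- rbind(c(1, 4), c(2, 5), c(3, 8), c(6, 7))
  } else {
    stop("predict_connectivity: hit has ", n,
         " cysteines; expected 6 (3DS) or 8 (4DS)")
  }
  data.frame(pos_a = cys[pairs[, 1]], pos_b = cys[pairs[, 2]],
             rank = seq_len(nrow(pairs)))
}

#' Quality-control filter for scanned sequences
#'
#' Classifies each record as kept (`OK`) or removed with a reason code,
#' mirroring the curation steps applied before alignment: sequences with
#' overlong inter-cysteine loops (`LONG_LOOP`), an unusually long N-terminus
#' before the first domain cysteine (`LONG_NTERM`), or too few cysteines to
#' form a domain (`MISSING_CYS`). Records with a domain hit are judged on the
#' hit; hit-less records are `MISSING_CYS` when they carry fewer cysteines
#' than the pattern requires, otherwise `LONG_LOOP` when some inter-cysteine
#' spacing exceeds `max_loop`, else `MISSING_CYS` (cysteines present but not
#' in a scaffold-compatible arrangement).
#'
#' @param records List of [seq_record()] objects.
#' @param hits Data frame of all hits from [scan_ick()] over `records`.
#' @param max_loop Maximum allowed inter-cysteine loop length (default 25).
#' @param max_nterm Maximum allowed N-terminal length before the first domain
#'   cysteine (default 60).
#' @param required_cys Cysteine count a domain needs (default 6).
#' @return Data frame with columns `id`, `kept`, `reason`.
#' @export
qc_filter <- function(records, hits, max_loop = 25L, max_nterm = 60L,
                      required_cys = 6L) {
  rows <- lapply(records, function(r) {
    h <- hits[hits$parent_id == r$id, , drop = FALSE]
    if (nrow(h) > 0) {
      loops <- unlist(lapply(seq_len(nrow(h)),
                             function(k) diff(hit_cys(h[k, ])) - 1L))
      if (any(loops > max_loop)) {
        reason <- "LONG_LOOP"
      } else if (min(h$start) - 1L > max_nterm) {
        reason <- "LONG_NTERM"
      } else {
        reason <- "OK"
      }
    } else {
      cys <- cys_positions_of(r$residues)
      if (length(cys) < required_cys) {
        reason <- "MISSING_CYS"
      } else if (any(diff(cys) - 1L > max_loop)) {
        reason <- "LONG_LOOP"
      } else {
        reason <- "MISSING_CYS"
      }
    }
    data.frame(id = r$id, kept = reason == "OK", reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
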