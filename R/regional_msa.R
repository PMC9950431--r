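#' Anchor a set of ICK domains on their conserved cysteines
#'
#' Collects domain records that share one cysteine count `k` and records each
#' sequence's cysteine offsets, ready for cysteine-anchored regional
#' alignment. With `k = NULL` (default) all records must agree on their
#' cysteine count, and mixed counts are an error listing the offenders; with
#' an explicit `k`, deviant records are rejected with a reason instead.
#'
#' @param domains List of [seq_record()] objects (typically from
#'   [split_domains()]).
#' @param k Expected cysteine count, or `NULL` to require unanimity.
#' @return An object of class `anchor_set`: `records`, `k`, `anchor_map`
#'   (list of length-`k` integer vectors), `rejected` (data frame `id`,
#'   `reason`).
#' @export
anchor_cysteines <- function(domains, k = NULL) {
  stopifnot(length(domains) >= 1)
  check_unique_ids(domains)
  counts <- vapply(domains, function(r) length(cys_positions_of(r$residues)),
                   integer(1))
  ids <- record_ids(domains)
  if (is.null(k)) {
    if (length(unique(counts)) > 1) {
      tab <- split(ids, counts)
      stop("mixed cysteine counts: ",
           paste(sprintf("%s cysteines: %s", names(tab),
                         vapply(tab, paste, character(1), collapse = ",")),
                 collapse = "; "))
    }
    k <- counts[1]
    keep <- rep(TRUE, length(domains))
  } else {
    keep <- counts == k
  }
  rejected <- data.frame(
    id = ids[!keep],
    reason = sprintf("has %d cysteines, expected %d", counts[!keep], k),
    stringsAsFactors = FALSE)
  records <- domains[keep]
  structure(list(
    records = records,
    k = as.integer(k),
    anchor_map = lapply(records, function(r) cys_positions_of(r$residues)),
    rejected = rejected
  ), class = "anchor_set")
}

kmer_counts <- function(s, k = 2L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

kmer_guide_order <- function(strings, ids) {
  # merge order for progressive alignment from 2-mer count distances;
  # ties broken by lexicographic id via the deterministic input ordering
  ord0 <- order(ids)
  strings <- strings[ord0]
  n <- length(strings)
  if (n <= 2) return(list(order = ord0, merges = NULL))
  kmers <- lapply(strings, kmer_counts)
  vocab <- sort(unique(unlist(kmers)))
  mat <- matrix(0, n, length(vocab))
  for (i in seq_len(n)) {
    t <- table(factor(kmers[[i]], levels = vocab))
    if (length(vocab) > 0) mat[i, ] <- as.numeric(t)
  }
  d <- dist(mat)
  hc <- hclust(d, method = "average")
  list(order = ord0, merges = hc$merge)
}

profile_col_score <- function(colA, colB, sub) {
  a <- colA[colA != "-"]
  b <- colB[colB != "-"]
  if (length(a) == 0 || length(b) == 0) return(0)
  mean(sub[a, b, drop = FALSE])
}

# global (Needleman-Wunsch) alignment of two profiles (character matrices),
# affine gaps costing gap_open + gap_ext * L; returns aligned column index
# paths (0 = gap)
nw_profile <- function(A, B, sub, gap_open = 11, gap_ext = 1) {
  nA <- ncol(A)
  nB <- ncol(B)
  if (nA == 0 || nB == 0) {
    return(list(pa = c(seq_len(nA), rep(0L, nB)),
                pb = c(rep(0L, nA), seq_len(nB))))
  }
  NEG <- -1e18
  M <- matrix(NEG, nA + 1, nB + 1)
  Ix <- matrix(NEG, nA + 1, nB + 1) # gap in B (consume A)
  Iy <- matrix(NEG, nA + 1, nB + 1) # gap in A (consume B)
  tM <- matrix(0L, nA + 1, nB + 1)
  tIx <- matrix(0L, nA + 1, nB + 1)
  tIy <- matrix(0L, nA + 1, nB + 1)
  M[1, 1] <- 0
  for (i in seq_len(nA)) { Ix[i + 1, 1] <- -(gap_open + gap_ext * i); tIx[i + 1, 1] <- 2L }
  for (j in seq_len(nB)) { Iy[1, j + 1] <- -(gap_open + gap_ext * j); tIy[1, j + 1] <- 3L }
  S <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    S[i, j] <- profile_col_score(A[, i], B[, j], sub)
  }
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      w <- which.max(cand)
      M[i + 1, j + 1] <- cand[w] + S[i, j]
      tM[i + 1, j + 1] <- w
      ox <- M[i, j + 1] - gap_open - gap_ext
      ex <- Ix[i, j + 1] - gap_ext
      if (ox >= ex) { Ix[i + 1, j + 1] <- ox; tIx[i + 1, j + 1] <- 1L }
      else { Ix[i + 1, j + 1] <- ex; tIx[i + 1, j + 1] <- 2L }
      oy <- M[i + 1, j] - gap_open - gap_ext
      ey <- Iy[i + 1, j] - gap_ext
      if (oy >= ey) { Iy[i + 1, j + 1] <- oy; tIy[i + 1, j + 1] <- 1L }
      else { Iy[i + 1, j + 1] <- ey; tIy[i + 1, j + 1] <- 3L }
    }
  }
  fin <- c(M[nA + 1, nB + 1], Ix[nA + 1, nB + 1], Iy[nA + 1, nB + 1])
  state <- which.max(fin)
  i <- nA; j <- nB
  pa <- integer(0); pb <- integer(0)
  while (i > 0 || j > 0) {
    if (state == 1L) {
      pa <- c(i, pa); pb <- c(j, pb)
      state <- tM[i + 1, j + 1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      pa <- c(i, pa); pb <- c(0L, pb)
      state <- tIx[i + 1, j + 1]
      i <- i - 1
    } else {
      pa <- c(0L, pa); pb <- c(j, pb)
      state <- tIy[i + 1, j + 1]
      j <- j - 1
    }
  }
  list(pa = pa, pb = pb)
}

merge_profiles <- function(A, B, path) {
  w <- length(path$pa)
  out <- matrix("-", nrow(A) + nrow(B), w)
  rownames(out) <- c(rownames(A), rownames(B))
  for (c in seq_len(w)) {
    if (path$pa[c] > 0) out[seq_len(nrow(A)), c] <- A[, path$pa[c]]
    if (path$pb[c] > 0) out[nrow(A) + seq_len(nrow(B)), c] <- B[, path$pb[c]]
  }
  out
}

# progressive profile alignment of a set of region strings; returns a
# character matrix with one row per input string, rows named by id and
# returned in input order
align_region_strings <- function(strings, ids, sub, gap_open = 11,
                                 gap_ext = 1) {
  n <- length(strings)
  widths <- nchar(strings)
  if (max(widths) <= 1) {
    # degenerate regions are copied verbatim, right-padded to equal width
    w <- max(widths)
    out <- matrix("-", n, w)
    for (i in seq_len(n)) {
      if (widths[i] > 0) out[i, seq_len(widths[i])] <- strsplit(strings[i], "")[[1]]
    }
    rownames(out) <- ids
    return(out)
  }
  as_profile <- function(i) {
    m <- matrix(if (widths[i] > 0) strsplit(strings[i], "")[[1]] else character(0),
                nrow = 1)
    rownames(m) <- ids[i]
    m
  }
  guide <- kmer_guide_order(strings, ids)
  if (is.null(guide$merges)) {
    prof <- as_profile(guide$order[1])
    for (i in guide$order[-1]) {
      nxt <- as_profile(i)
      prof <- merge_profiles(prof, nxt,
                             nw_profile(prof, nxt, sub, gap_open, gap_ext))
    }
  } else {
    nodes <- vector("list", nrow(guide$merges))
    for (m in seq_len(nrow(guide$merges))) {
      get <- function(x) if (x < 0) as_profile(guide$order[-x]) else nodes[[x]]
      A <- get(guide$merges[m, 1])
      B <- get(guide$merges[m, 2])
      nodes[[m]] <- merge_profiles(A, B, nw_profile(A, B, sub, gap_open, gap_ext))
    }
    prof <- nodes[[length(nodes)]]
  }
  prof[ids, , drop = FALSE]
}

#' Cysteine-anchored regional multiple alignment
#'
#' Builds a multiple alignment in which the `k` conserved cysteines occupy
#' fixed single-residue anchor columns and the `k + 1` pre-, inter-, and
#' post-cysteine regions are aligned independently by progressive profile
#' alignment (guide order from 2-mer count distances, BLOSUM62, affine
#' gaps). Regions whose width never exceeds one residue bypass alignment and
#' are copied verbatim. Anchor columns therefore contain only `C`, and
#' degapping any row reproduces its input sequence.
#'
#' @param anchors An `anchor_set` from [anchor_cysteines()].
#' @param gap_open,gap_ext Affine gap penalties (defaults 11 and 1).
#' @return An object of class `regional_alignment`: `ids`, `aln` (named
#'   character vector of gapped rows), `anchor_cols` (k column indices),
#'   `region_blocks` (data frame `start`, `end`, half-open column ranges,
#'   zero-width allowed), `width`.
#' @export
align_regions <- function(anchors, gap_open = 11, gap_ext = 1) {
  stopifnot(inherits(anchors, "anchor_set"))
  sub <- blosum62_matrix()
  k <- anchors$k
  ids <- record_ids(anchors$records)
  n <- length(ids)
  region_string <- function(rec, map, r) {
    # region r in 0..k: before C1, between C_r and C_{r+1}, after C_k
    from <- if (r == 0) 1L else map[r] + 1L
    to <- if (r == k) nchar(rec$residues) else map[r + 1L] - 1L
    if (to < from) "" else substr(rec$residues, from, to)
  }
  blocks <- vector("list", k + 1L)
  for (r in 0:k) {
    strings <- vapply(seq_len(n), function(i) {
      region_string(anchors$records[[i]], anchors$anchor_map[[i]], r)
    }, character(1))
    blocks[[r + 1L]] <- align_region_strings(strings, ids, sub,
                                             gap_open, gap_ext)
  }
  rows <- character(n)
  anchor_cols <- integer(k)
  block_ranges <- data.frame(start = integer(k + 1L), end = integer(k + 1L))
  pos <- 0L
  parts <- vector("list", n)
  for (i in seq_len(n)) parts[[i]] <- character(0)
  for (r in 0:k) {
    bw <- ncol(blocks[[r + 1L]])
    block_ranges$start[r + 1L] <- pos + 1L
    block_ranges$end[r + 1L] <- pos + bw
    for (i in seq_len(n)) {
      parts[[i]] <- c(parts[[i]], blocks[[r + 1L]][ids[i], ])
    }
    pos <- pos + bw
    if (r < k) {
      pos <- pos + 1L
      anchor_cols[r + 1L] <- pos
      for (i in seq_len(n)) parts[[i]] <- c(parts[[i]], "C")
    }
  }
  rows <- vapply(parts, paste, character(1), collapse = "")
  structure(list(ids = ids, aln = setNames(rows, ids),
                 anchor_cols = anchor_cols, region_blocks = block_ranges,
                 width = pos),
            class = "regional_alignment")
}

#' @export
print.regional_alignment <- function(x, ...) {
  cat(sprintf("<regional_alignment> %d sequences x %d columns, %d anchors\n",
              length(x$ids), x$width, length(x$anchor_cols)))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln A `regional_alignment`.
#' @return Character matrix, rows = sequences, columns = alignment columns.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "regional_alignment"))
  m <- do.call(rbind, strsplit(aln$aln, ""))
  rownames(m) <- aln$ids
  m
}

CLUSTAL_STRONG <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                    "HY", "FYW")
CLUSTAL_WEAK <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                  "NDEQHK", "NEQHRK", "FVLIM", "HFY")

#' Clustal-style conservation line for an alignment
#'
#' `*` marks a column of one residue type with no gaps; `:` a gap-free
#' column whose residues all fall within one Clustal strong group; `.` one
#' weak group; space otherwise. Any gap in a column forbids all three
#' symbols.
#'
#' @param aln A `regional_alignment` (or character matrix of gapped rows).
#' @return Single string over `* : . ' '` of alignment width.
#' @export
conservation_line <- function(aln) {
  m <- if (inherits(aln, "regional_alignment")) alignment_matrix(aln) else aln
  stopifnot(is.matrix(m), nrow(m) >= 1)
  strong_sets <- strsplit(CLUSTAL_STRONG, "")
  weak_sets <- strsplit(CLUSTAL_WEAK, "")
  sym <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-")) return(" ")
    u <- unique(col)
    if (length(u) == 1) return("*")
    if (any(vapply(strong_sets, function(g) all(u %in% g), logical(1)))) {
      return(":")
    }
    if (any(vapply(weak_sets, function(g) all(u %in% g), logical(1)))) {
      return(".")
    }
    " "
  }, character(1))
  paste(sym, collapse = "")
}

#' Read an aligned FASTA into a character matrix
#'
#' Rows may contain `-` gap characters; all rows must share one width.
#'
#' @param path Aligned FASTA path.
#' @return Character matrix, rows named by record id.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) stop("no records in ", path)
  bounds <- c(heads, length(lines) + 1L)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[heads]))
  rows <- vapply(seq_along(heads), function(k) {
    gsub("\\s", "", paste(lines[seq.int(bounds[k] + 1L, bounds[k + 1L] - 1L)],
                          collapse = ""))
  }, character(1))
  if (length(unique(nchar(rows))) != 1) {
    stop("alignment rows differ in width")
  }
  bad <- setdiff(unique(unlist(strsplit(rows, ""))),
                 c(AA_ALPHABET20, "X", "-"))
  if (length(bad) > 0) stop("illegal alignment character(s): ",
                            paste(bad, collapse = ", "))
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- ids
  m
}

#' Write a regional alignment as aligned FASTA
#'
#' @param aln A `regional_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in aln$ids) {
    writeLines(c(paste0(">", id), aln$aln[[id]]), con, sep = "\n")
  }
  invisible(path)
}
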