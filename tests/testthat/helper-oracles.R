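# Independent reference implementations used as test oracles. These are
# deliberately written as plain, direct translations of the declared
# algorithms (brute force where possible) and share no code with the
# package internals they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA19 <- setdiff(AA20, "C")

random_peptide <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_dna <- function(len, with_n = FALSE) {
  ab <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(ab, len, replace = TRUE), collapse = "")
}

# --- brute-force six-frame ORF enumeration ---------------------------------

oracle_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- setNames(as.character(gc), names(gc))
    }
    tab
  }
})

oracle_translate_frame <- function(dna, off) {
  tab <- oracle_codon_table()
  n <- nchar(dna)
  n_codon <- (n - off) %/% 3
  if (n_codon < 1) return("")
  aa <- character(n_codon)
  for (k in seq_len(n_codon)) {
    codon <- substr(dna, off + (k - 1) * 3 + 1, off + k * 3)
    aa[k] <- if (grepl("N", codon)) "X" else tab[[codon]]
  }
  paste(aa, collapse = "")
}

oracle_revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "")[[1]]), collapse = "")
}

oracle_orfs <- function(dna, min_len) {
  out <- character(0)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else oracle_revcomp(dna)
    for (off in 0:2) {
      aa <- oracle_translate_frame(s, off)
      for (piece in strsplit(aa, "*", fixed = TRUE)[[1]]) {
        if (nchar(piece) >= min_len) out <- c(out, piece)
      }
    }
  }
  sort(out)
}

# --- exhaustive cysteine-window scan ---------------------------------------

oracle_scan <- function(residues, n_cys, bounds) {
  cys <- which(strsplit(residues, "")[[1]] == "C")
  hits <- list()
  i <- 1
  while (i + n_cys - 1 <= length(cys)) {
    w <- cys[i:(i + n_cys - 1)]
    sp <- diff(w) - 1
    if (all(sp >= bounds[, 1] & sp <= bounds[, 2])) {
      hits[[length(hits) + 1]] <- c(start = w[1], end = w[n_cys])
      i <- i + n_cys
    } else {
      i <- i + 1
    }
  }
  hits
}

# --- quadratic banded-excluded local self-alignment ------------------------

oracle_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# full Smith-Waterman over the upper triangle with j - i >= band, affine
# gaps costing open + ext * L; returns NULL or list(score, span_a, span_b,
# identity)
oracle_self_align <- function(res, band, open = 11, ext = 1,
                              mask = rep(FALSE, length(res))) {
  sub <- oracle_blosum62()
  n <- length(res)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, n + 1)
  Ix <- matrix(NEG, n + 1, n + 1)
  Iy <- matrix(NEG, n + 1, n + 1)
  best <- 0
  bi <- bj <- 0
  for (i in seq_len(n)) {
    jmin <- i + band
    if (jmin > n) next
    for (j in jmin:n) {
      if (mask[i] || mask[j]) next
      M[i + 1, j + 1] <- sub[res[i], res[j]] +
        max(0, M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]
        bi <- i; bj <- j
      }
    }
  }
  if (bi == 0) return(NULL)
  # traceback by recomputation
  i <- bi; j <- bj; state <- "M"
  ai <- integer(0); aj <- integer(0)
  repeat {
    if (state == "M") {
      ai <- c(i, ai); aj <- c(j, aj)
      prev <- c(0, M[i, j], Ix[i, j], Iy[i, j])
      w <- which.max(prev)
      i <- i - 1; j <- j - 1
      if (w == 1) break
      state <- c("", "M", "Ix", "Iy")[w]
    } else if (state == "Ix") {
      ai <- c(i, ai); aj <- c(0, aj)
      from_open <- M[i, j + 1] - open - ext
      from_ext <- Ix[i, j + 1] - ext
      state <- if (from_open >= from_ext) "M" else "Ix"
      i <- i - 1
    } else {
      ai <- c(0, ai); aj <- c(j, aj)
      from_open <- M[i + 1, j] - open - ext
      from_ext <- Iy[i + 1, j] - ext
      state <- if (from_open >= from_ext) "M" else "Iy"
      j <- j - 1
    }
    if (i == 0 || j == 0) break
  }
  both <- ai > 0 & aj > 0
  ident <- 100 * sum(both & res[pmax(ai, 1)] == res[pmax(aj, 1)]) / length(ai)
  list(score = best,
       span_a = range(ai[ai > 0]), span_b = range(aj[aj > 0]),
       identity = ident, ai = ai, aj = aj)
}

# brute-force O(P^3) search for the best-scoring non-overlapping window of
# an alignment path: every (u, v) window is scored from scratch with affine
# gap-run costs; ties prefer longer windows, then smaller u
oracle_trim_window <- function(ai, aj, res, open = 11, ext = 1) {
  sub <- oracle_blosum62()
  P <- length(ai)
  best <- NULL
  for (u in seq_len(P)) {
    for (v in u:P) {
      ii <- ai[u:v]
      jj <- aj[u:v]
      if (!any(ii > 0) || !any(jj > 0)) next
      if (max(ii) >= min(jj[jj > 0])) next
      score <- 0
      prev <- ""
      for (c in seq_along(ii)) {
        type <- if (jj[c] == 0) "Ix" else if (ii[c] == 0) "Iy" else "M"
        score <- score + if (type == "M") {
          sub[res[ii[c]], res[jj[c]]]
        } else if (type == prev) {
          -ext
        } else {
          -(open + ext)
        }
        prev <- type
      }
      len <- v - u + 1
      if (is.null(best) || score > best$score ||
          (score == best$score && (len > best$len ||
           (len == best$len && u < best$u)))) {
        best <- list(score = score, u = u, v = v, len = len)
      }
    }
  }
  best
}

# iterated call mimicking the declared repeat-detection loop (including the
# trim-to-non-overlap rule), for set comparison with
# detect_internal_repeats()
oracle_repeat_calls <- function(residues, min_identity = 40,
                                min_unit_len = 20, max_rounds = 3) {
  res <- strsplit(residues, "")[[1]]
  mask <- rep(FALSE, length(res))
  calls <- list()
  for (round in seq_len(max_rounds)) {
    al <- oracle_self_align(res, min_unit_len, mask = mask)
    if (is.null(al) || al$score <= 0) break
    if (al$span_a[2] >= al$span_b[1]) {
      w <- oracle_trim_window(al$ai, al$aj, res)
      if (is.null(w) || w$score <= 0) break
      ai <- al$ai[w$u:w$v]
      aj <- al$aj[w$u:w$v]
      both <- ai > 0 & aj > 0
      al <- list(score = w$score,
                 span_a = range(ai[ai > 0]), span_b = range(aj[aj > 0]),
                 identity = 100 * sum(both &
                   res[pmax(ai, 1)] == res[pmax(aj, 1)]) / length(ai),
                 ai = ai, aj = aj)
    }
    len_a <- diff(al$span_a) + 1
    len_b <- diff(al$span_b) + 1
    if (al$identity < min_identity || len_a < min_unit_len ||
        len_b < min_unit_len || al$span_a[2] >= al$span_b[1]) break
    calls[[length(calls) + 1]] <- al
    mask[al$span_a[1]:al$span_a[2]] <- TRUE
    mask[al$span_b[1]:al$span_b[2]] <- TRUE
  }
  calls
}

# --- direct Clustal conservation lookup ------------------------------------

oracle_conservation <- function(mat) {
  strong <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF", "HY",
              "FYW")
  weak <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK", "NDEQHK",
            "NEQHRK", "FVLIM", "HFY")
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (any(col == "-")) return(" ")
    u <- unique(col)
    if (length(u) == 1) return("*")
    in_group <- function(groups) {
      any(vapply(strsplit(groups, ""), function(g) all(u %in% g), logical(1)))
    }
    if (in_group(strong)) ":" else if (in_group(weak)) "." else " "
  }, character(1))
}

# --- misc builders ----------------------------------------------------------

withr_tempfile <- function() tempfile(fileext = ".fa")

# point-mutate each unprotected site with probability p (to a different
# non-cysteine residue); returns a character vector of residues
mutate_for_test <- function(s, p, protect = integer(0)) {
  res <- strsplit(s, "")[[1]]
  idx <- setdiff(which(runif(length(res)) < p), protect)
  for (i in idx) res[i] <- sample(setdiff(AA19, res[i]), 1)
  res
}

record_ids_for_test <- function(recs) {
  vapply(recs, function(r) r$id, character(1))
}

# a scaffold-like domain string: cysteine-bounded, spacings within the
# default 3-DS bounds
make_domain_string <- function(spacings = c(6, 6, 0, 4, 10)) {
  loops <- vapply(spacings, function(s) {
    if (s == 0) "" else random_peptide(s, AA19)
  }, character(1))
  paste0("C", paste(vapply(seq_along(loops), function(i) {
    paste0(loops[i], "C")
  }, character(1)), collapse = ""))
}

# substitute exactly k non-cysteine positions of a peptide (to a different
# residue), returning the mutated string
substitute_k <- function(s, k) {
  res <- strsplit(s, "")[[1]]
  cand <- which(res != "C")
  pick <- sample(cand, min(k, length(cand)))
  for (i in pick) {
    res[i] <- sample(setdiff(AA19, res[i]), 1)
  }
  paste(res, collapse = "")
}
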