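#' Load the per-residue biophysical property table
#'
#' Six descriptors per amino acid: molecular weight (Da, free amino acid),
#' integer net charge at pH 7 (K, R = +1; D, E = -1; H and all others = 0),
#' Kyte-Doolittle hydropathy, TOP-IDP disorder propensity, and a binary
#' disulfide potential (1 for cysteine). The sixth descriptor, occupancy, is
#' assigned during featurisation (1 for a residue, 0 for a gap). The table
#' ships as a versioned CSV; pass `path` to substitute another table with the
#' same columns.
#'
#' @param path Optional path to an alternative CSV.
#' @return Data frame with row names = amino-acid letters and columns `mw`,
#'   `charge`, `kd_hydro`, `top_idp`, `ss_potential`.
#' @export
property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "biophysical_properties.csv",
                        package = "knotminer", mustWork = TRUE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("aa", "mw", "charge", "kd_hydro", "top_idp", "ss_potential")
  if (!all(need %in% names(tab))) {
    stop("property table must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(tab$aa, AA_ALPHABET20)) {
    stop("property table must cover exactly the 20 standard amino acids")
  }
  rownames(tab) <- tab$aa
  tab[AA_ALPHABET20, setdiff(need, "aa")]
}

PROPERTY_NAMES <- c("mw", "charge", "kd_hydro", "top_idp", "ss_potential",
                    "occupancy")

#' Encode an alignment as a biophysical feature matrix
#'
#' Every alignment cell expands into six numeric features: the five physical
#' properties of its residue plus occupancy 1; a gap contributes zeros for
#' all six. Residues absent from the property table (e.g. `X`) contribute
#' zeros for the five physical properties but occupancy 1, with a warning
#' (or an error when `on_unknown = "error"`).
#'
#' @param aln A `regional_alignment` or character matrix of gapped rows.
#' @param table Property table from [property_table()].
#' @param on_unknown `"zero"` (default, warn) or `"error"`.
#' @return Numeric matrix, rows = sequences, columns named
#'   `pos<j>_<property>` (alignment width x 6 columns).
#' @export
featurize <- function(aln, table = property_table(),
                      on_unknown = c("zero", "error")) {
  on_unknown <- match.arg(on_unknown)
  m <- if (inherits(aln, "regional_alignment")) alignment_matrix(aln) else aln
  stopifnot(is.matrix(m), nrow(m) >= 1, ncol(m) >= 1)
  unknown <- setdiff(unique(as.vector(m)), c(rownames(table), "-"))
  if (length(unknown) > 0) {
    msg <- paste0("residue(s) not in property table: ",
                  paste(unknown, collapse = ", "))
    if (on_unknown == "error") stop(msg)
    warning(msg, "; physical properties zero-filled")
  }
  nprop <- length(PROPERTY_NAMES)
  out <- matrix(0, nrow(m), ncol(m) * nprop)
  rownames(out) <- rownames(m)
  colnames(out) <- as.vector(t(outer(seq_len(ncol(m)), PROPERTY_NAMES,
                                     function(j, p) paste0("pos", j, "_", p))))
  phys <- as.matrix(table)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    block <- matrix(0, nrow(m), nprop)
    hit <- match(col, rownames(table))
    known <- !is.na(hit)
    block[known, 1:5] <- phys[hit[known], ]
    block[col != "-", 6] <- 1
    out[, (j - 1) * nprop + seq_len(nprop)] <- block
  }
  out
}

#' Principal-component projection of a feature matrix
#'
#' Columns are centered and scaled to unit variance (constant columns are
#' dropped and recorded), the covariance eigendecomposition is taken, and
#' the top `n_components` are retained. Signs follow the convention that
#' each component's largest-magnitude loading is positive.
#'
#' @param X Numeric feature matrix (rows = sequences, >= 2 rows).
#' @param n_components Number of components to retain (default 3).
#' @return List of class `pca_result`: `scores` (rows x n_components),
#'   `loadings` (kept columns x n_components), `explained` (variance
#'   fractions for all computed components, descending), `dropped`
#'   (names of constant columns), `center`, `scale`.
#' @export
pca_project <- function(X, n_components = 3L) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2) stop("pca_project needs at least 2 rows")
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  dropped <- colnames(X)[!keep]
  Xk <- X[, keep, drop = FALSE]
  pc <- prcomp(Xk, center = TRUE, scale. = TRUE)
  n_components <- min(n_components, ncol(pc$rotation))
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (c in seq_len(n_components)) {
    s <- sign(loadings[which.max(abs(loadings[, c])), c])
    if (s < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, dropped = dropped,
                 center = pc$center, scale = pc$scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d sequences, %d components (%.1f%% variance), %d constant columns dropped\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained[seq_len(ncol(x$scores))]),
              length(x$dropped)))
  invisible(x)
}

#' Ranked physicochemical neighbours of a query sequence
#'
#' Euclidean distance in principal-component score space, either the
#' retained components (`space = "3pc"`, the default three-component
#' projection) or all retained score columns (`space = "full"`, identical
#' unless the result holds more than the projection). Ties break by id; the
#' query never appears in its own list.
#'
#' @param result A `pca_result`.
#' @param query Id (row name) of the query sequence.
#' @param k Number of neighbours (default 10). When `k` is at least the
#'   number of other sequences, all are returned with a note attribute.
#' @param space `"3pc"` or `"full"`.
#' @return Data frame `id`, `distance`, `rank` (distances nondecreasing),
#'   with attribute `query`.
#' @export
nearest_neighbors <- function(result, query, k = 10L,
                              space = c("3pc", "full")) {
  space <- match.arg(space)
  stopifnot(inherits(result, "pca_result"))
  S <- result$scores
  if (space == "3pc") S <- S[, seq_len(min(3L, ncol(S))), drop = FALSE]
  if (!query %in% rownames(S)) stop("query '", query, "' not found")
  q <- S[query, ]
  others <- setdiff(rownames(S), query)
  dvec <- sqrt(colSums((t(S[others, , drop = FALSE]) - q)^2))
  ord <- order(dvec, others)
  note <- NULL
  if (k >= length(others)) {
    note <- sprintf("only %d other sequences; returning all", length(others))
    k <- length(others)
  }
  sel <- ord[seq_len(k)]
  out <- data.frame(id = others[sel], distance = unname(dvec[sel]),
                    rank = seq_len(k), stringsAsFactors = FALSE)
  attr(out, "query") <- query
  if (!is.null(note)) attr(out, "note") <- note
  out
}
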