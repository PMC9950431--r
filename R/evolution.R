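#' Kimura-corrected protein distance matrix
#'
#' For every sequence pair, computes the p-distance over mutually ungapped
#' columns and applies Kimura's empirical protein correction
#' `d = -ln(1 - p - 0.2 p^2)`. Saturated pairs (where the argument of the
#' logarithm drops to `sat_floor` or below) are capped at `-ln(sat_floor)`.
#'
#' @param aln A `regional_alignment` (or character matrix of gapped rows).
#' @param sat_floor Saturation floor for the log argument (default 0.01, so
#'   distances cap at `-ln(0.01)`).
#' @param on_empty What to do for a pair with zero mutually ungapped columns:
#'   `"error"` (default) names the pair, `"cap"` assigns the capped maximum.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
protein_distance <- function(aln, sat_floor = 0.01,
                             on_empty = c("error", "cap")) {
  on_empty <- match.arg(on_empty)
  m <- if (inherits(aln, "regional_alignment")) alignment_matrix(aln) else aln
  stopifnot(is.matrix(m), nrow(m) >= 2)
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  dmax <- -log(sat_floor)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      nshared <- sum(ok)
      if (nshared == 0) {
        if (on_empty == "error") {
          stop("no mutually ungapped columns for pair ",
               ids[i], " / ", ids[j])
        }
        dij <- dmax
      } else {
        p <- sum(m[i, ok] != m[j, ok]) / nshared
        arg <- 1 - p - 0.2 * p^2
        dij <- if (arg <= sat_floor) dmax else -log(arg)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]) with negative branch
#' lengths clamped to zero. Taxa are processed in lexicographic id order so
#' ties resolve deterministically.
#'
#' @param d Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An [ape::read.tree()]-style `phylo` object.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3, !is.null(rownames(d)))
  ord <- order(rownames(d))
  tree <- ape::nj(d[ord, ord])
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

resample_columns <- function(m, cols) {
  out <- m[, cols, drop = FALSE]
  rownames(out) <- rownames(m)
  out
}

#' Neighbour-joining tree with nonparametric bootstrap supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds an NJ tree per
#' replicate, and scores each internal edge of the point tree by the
#' percentage of replicate trees containing the same bipartition. Internal
#' edges with support below `collapse_below` are collapsed into
#' multifurcations. Saturated or column-starved replicate pairs fall back to
#' the capped maximum distance so every replicate yields a tree.
#'
#' @param aln A `regional_alignment` or character matrix of gapped rows
#'   (>= 4 sequences for meaningful bipartitions).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; resampling is fully determined by it.
#' @param collapse_below Support percentage below which internal branches
#'   are collapsed (default 50); `NULL` disables collapsing.
#' @return A `phylo` tree whose `node.label` holds integer percent supports
#'   (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              collapse_below = 50) {
  m <- if (inherits(aln, "regional_alignment")) alignment_matrix(aln) else aln
  stopifnot(is.matrix(m), n_reps >= 1)
  point <- nj_tree(protein_distance(m, on_empty = "cap"))
  ncol_m <- ncol(m)
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol_m, ncol_m, replace = TRUE)
    boots[[b]] <- nj_tree(protein_distance(resample_columns(m, cols),
                                           on_empty = "cap"))
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps)
  point$node.label <- as.character(support)
  point$node.label[1] <- "" # root of the unrooted representation
  if (!is.null(collapse_below)) {
    point <- phangorn::pruneTree(point, collapse_below,
                                 FUN = function(x, y) as.numeric(x) >= y)
  }
  point
}

discrete_gamma_rates <- function(alpha, k) {
  # mean rate of each of k equal-probability bins of Gamma(alpha, alpha)
  if (k == 1) return(1)
  q <- qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  p_upper <- stats::pgamma(c(q, Inf), shape = alpha + 1, rate = alpha)
  k * diff(c(0, p_upper))
}

poisson_pmatrix_terms <- function(rt) {
  # 20-state Poisson model scaled to one expected substitution per unit
  # time: P(same) = (1 + 19 e^{-20/19 rt})/20, P(each other) = (1 - e)/20
  e <- exp(-20 / 19 * rt)
  list(same = (1 + 19 * e) / 20, diff = (1 - e) / 20)
}

column_loglik <- function(states, tree, rate) {
  # Felsenstein pruning for one column under the Poisson model; `states`
  # holds 1..20 per leaf (NA = gap/unknown, a vector of ones)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  partial <- matrix(1, nnode, 20)
  known <- !is.na(states)
  partial[which(known), ] <- 0
  partial[cbind(which(known), states[known])] <- 1
  edge <- tree$edge
  elen <- tree$edge.length
  for (k in ape::postorder(tree)) {
    parent <- edge[k, 1]
    child <- edge[k, 2]
    pm <- poisson_pmatrix_terms(rate * elen[k])
    down <- partial[child, ]
    tot <- sum(down)
    # P %*% down for the equal-off-diagonal matrix
    contrib <- pm$diff * tot + (pm$same - pm$diff) * down
    partial[parent, ] <- partial[parent, ] * contrib
  }
  root <- ntip + 1L
  lik <- sum(partial[root, ]) / 20
  log(lik)
}

#' Site-specific substitution rates by discrete-gamma maximum likelihood
#'
#' Computes per-column likelihoods on a fixed tree by the pruning algorithm
#' under a Poisson amino-acid model (uniform exchangeabilities and
#' frequencies) across `n_categories` discrete-gamma rate categories. Each
#' scored column's rate is the posterior-mean category rate; the gamma shape
#' `alpha` is optimised by bounded one-dimensional maximisation of the total
#' log-likelihood when not supplied. Rates are normalised to mean one over
#' scored columns; all-gap columns are flagged unscored (`NA` rate).
#'
#' @param aln A `regional_alignment` or character matrix.
#' @param tree A `phylo` tree whose tips match the alignment ids.
#' @param n_categories Number of discrete-gamma categories (default 4).
#' @param alpha Gamma shape; `NULL` (default) optimises it in (0.05, 50).
#' @return List of class `site_rate_profile`: `rate` (numeric per column,
#'   `NA` when unscored), `scored` (logical), `alpha`, `loglik`.
#' @export
site_rates <- function(aln, tree, n_categories = 4L, alpha = NULL) {
  m <- if (inherits(aln, "regional_alignment")) alignment_matrix(aln) else aln
  stopifnot(is.matrix(m))
  if (!setequal(tree$tip.label, rownames(m))) {
    stop("tree tips do not match alignment ids")
  }
  m <- m[tree$tip.label, , drop = FALSE]
  state_idx <- matrix(match(m, AA_ALPHABET20), nrow(m), ncol(m))
  scored <- colSums(!is.na(state_idx)) > 0
  total_ll <- function(a) {
    rates <- discrete_gamma_rates(a, n_categories)
    sum(vapply(which(scored), function(j) {
      lls <- vapply(rates, function(r) column_loglik(state_idx[, j], tree, r),
                    numeric(1))
      mx <- max(lls)
      mx + log(mean(exp(lls - mx)))
    }, numeric(1)))
  }
  if (is.null(alpha)) {
    alpha <- optimize(total_ll, interval = c(0.05, 50), maximum = TRUE,
                      tol = 1e-3)$maximum
  }
  rates <- discrete_gamma_rates(alpha, n_categories)
  rate <- rep(NA_real_, ncol(m))
  ll_total <- 0
  for (j in which(scored)) {
    lls <- vapply(rates, function(r) column_loglik(state_idx[, j], tree, r),
                  numeric(1))
    mx <- max(lls)
    w <- exp(lls - mx)
    rate[j] <- sum(rates * w) / sum(w)
    ll_total <- ll_total + mx + log(mean(w))
  }
  rate[scored] <- rate[scored] / mean(rate[scored])
  structure(list(rate = rate, scored = scored, alpha = alpha,
                 loglik = ll_total),
            class = "site_rate_profile")
}

#' @export
print.site_rate_profile <- function(x, ...) {
  cat(sprintf("<site_rate_profile> %d/%d columns scored, alpha = %.3f, logL = %.3f\n",
              sum(x$scored), length(x$rate), x$alpha, x$loglik))
  invisible(x)
}
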