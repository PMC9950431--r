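aln_matrix <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  m
}

test_that("protein distances follow the Kimura closed form", {
  m <- aln_matrix(c(a = strrep("A", 50), b = strrep("A", 50)))
  expect_equal(unname(protein_distance(m)["a", "b"]), 0)
  # p = 0.1: 5 mismatches in 50 columns
  m2 <- aln_matrix(c(a = strrep("A", 50),
                     b = paste0(strrep("R", 5), strrep("A", 45))))
  expect_equal(unname(protein_distance(m2)["a", "b"]),
               -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)
  # saturation: p = 1 caps at -ln(0.01)
  m3 <- aln_matrix(c(a = strrep("A", 30), b = strrep("R", 30)))
  expect_equal(unname(protein_distance(m3)["a", "b"]), -log(0.01))
  # a pair with no shared ungapped columns errors, naming the pair
  m4 <- aln_matrix(c(a = "AA--", b = "--RR"))
  expect_error(protein_distance(m4), "a / b")
  expect_equal(unname(protein_distance(m4, on_empty = "cap")["a", "b"]),
               -log(0.01))
})

test_that("Kimura-corrected distances track simulated substitution counts", {
  # independent event-level simulator: Poisson(t * L) substitution events,
  # each changing a random site to a uniformly different residue
  set.seed(81)
  L <- 2000
  for (t_true in c(0.05, 0.1, 0.2, 0.3)) {
    errs <- vapply(1:25, function(rep) {
      anc <- sample(AA20, L, replace = TRUE)
      der <- anc
      for (e in seq_len(stats::rpois(1, t_true * L))) {
        site <- sample.int(L, 1)
        der[site] <- sample(setdiff(AA20, der[site]), 1)
      }
      m <- rbind(a = anc, b = der)
      unname(protein_distance(m)["a", "b"]) - t_true
    }, numeric(1))
    expect_lt(abs(mean(errs)) / t_true, 0.1)
  }
})

test_that("neighbour joining is exact on an additive 4-taxon matrix", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.05);")
  d <- cophenetic(tr)
  nj <- nj_tree(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  expect_equal(cophenetic(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("an equidistant matrix resolves with zero-length internal edges", {
  d <- matrix(1, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  diag(d) <- 0
  tr <- nj_tree(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(tr$edge.length[internal] < 1e-12))
  expect_error(nj_tree(d[1:2, 1:2]), ".")
})

test_that("bootstrap supports separate clearly split clades", {
  set.seed(82)
  cfg <- sim_config(seed = 82)
  anc <- make_scaffold(cfg, "anc")
  cys <- attr(anc, "cys_positions")
  rates <- rep(1, nchar(anc$residues))
  rates[cys] <- 0
  # two 5-taxon clades: long internal stem, short within-clade branches
  tr <- ape::read.tree(text = paste0(
    "((a1:0.02,a2:0.02,a3:0.02,a4:0.02,a5:0.02):0.6,",
    "(b1:0.02,b2:0.02,b3:0.02,b4:0.02,b5:0.02):0.6);"))
  fam <- evolve_family(anc, tr, rates, "split")
  aln <- align_regions(anchor_cysteines(fam$records))
  bt <- bootstrap_support(aln, n_reps = 200, seed = 9, collapse_below = NULL)
  # the clade separating a* from b* must be near-unanimous
  labs <- as.numeric(bt$node.label[nzchar(bt$node.label)])
  part <- ape::prop.part(bt)
  tips <- bt$tip.label
  a_tips <- grep("_a", tips)
  found <- FALSE
  for (i in seq_along(part)) {
    side <- part[[i]]
    if (setequal(side, a_tips) || setequal(side, setdiff(seq_along(tips), a_tips))) {
      node <- attr(part, "number")[i]
      found <- TRUE
    }
  }
  expect_true(found)
  expect_true(any(labs >= 95))
})

test_that("single-replicate bootstraps give all-or-nothing supports", {
  set.seed(83)
  m <- matrix(sample(AA20, 6 * 40, replace = TRUE), 6, 40,
              dimnames = list(paste0("t", 1:6), NULL))
  bt <- bootstrap_support(m, n_reps = 1, seed = 4, collapse_below = NULL)
  labs <- as.numeric(bt$node.label[nzchar(bt$node.label)])
  expect_true(all(labs %in% c(0, 100)))
})

test_that("a fixed seed makes the bootstrap newick byte-identical", {
  set.seed(84)
  m <- matrix(sample(AA20, 8 * 60, replace = TRUE), 8, 60,
              dimnames = list(paste0("t", 1:8), NULL))
  n1 <- ape::write.tree(bootstrap_support(m, n_reps = 50, seed = 11))
  n2 <- ape::write.tree(bootstrap_support(m, n_reps = 50, seed = 11))
  expect_identical(n1, n2)
})

test_that("low-support branches are collapsed into multifurcations", {
  set.seed(85)
  m <- matrix(sample(AA20, 8 * 12, replace = TRUE), 8, 12,
              dimnames = list(paste0("t", 1:8), NULL))
  full <- bootstrap_support(m, n_reps = 100, seed = 2, collapse_below = NULL)
  coll <- bootstrap_support(m, n_reps = 100, seed = 2, collapse_below = 50)
  labs <- as.numeric(coll$node.label[nzchar(coll$node.label)])
  expect_true(all(labs >= 50))
  expect_lte(coll$Nnode, full$Nnode)
})

test_that("pruning likelihood matches the two-taxon closed form", {
  tr <- ape::read.tree(text = "(A:0.13,B:0.27);")
  # same residue in both taxa, and different residues
  m_same <- aln_matrix(c(A = "K", B = "K"))
  m_diff <- aln_matrix(c(A = "K", B = "W"))
  for (r in c(0.2, 1, 3.7)) {
    tt <- r * (0.13 + 0.27)
    e <- exp(-20 / 19 * tt)
    want_same <- log((1 / 20) * (1 + 19 * e) / 20)
    want_diff <- log((1 / 20) * (1 - e) / 20)
    # with one category the category rate is 1; rescale branches by r
    tr_r <- tr
    tr_r$edge.length <- tr$edge.length * r
    expect_equal(site_rates(m_same, tr_r, n_categories = 1)$loglik,
                 want_same, tolerance = 1e-10)
    expect_equal(site_rates(m_diff, tr_r, n_categories = 1)$loglik,
                 want_diff, tolerance = 1e-10)
  }
})

test_that("conserved columns score lower rates than variable ones", {
  set.seed(86)
  tr <- ape::rtree(8)
  tips <- tr$tip.label
  cons <- setNames(rep("K", 8), tips)
  vary <- setNames(sample(AA20, 8), tips)
  m <- cbind(cons, vary)
  m <- matrix(c(cons, vary), nrow = 8, dimnames = list(tips, NULL))
  sr <- site_rates(m, tr, alpha = 0.7)
  expect_lt(sr$rate[1], sr$rate[2])
  expect_equal(mean(sr$rate[sr$scored]), 1, tolerance = 1e-9)
})

test_that("all-gap columns are flagged unscored", {
  tips <- paste0("t", 1:4)
  m <- matrix(c(rep("A", 4), rep("-", 4), sample(AA20, 4)), 4,
              dimnames = list(tips, NULL))
  tr <- ape::rtree(4)
  tr$tip.label <- tips
  sr <- site_rates(m, tr, alpha = 1)
  expect_false(sr$scored[2])
  expect_true(is.na(sr$rate[2]))
  expect_equal(mean(sr$rate[sr$scored]), 1, tolerance = 1e-9)
})

test_that("total log-likelihood is invariant to leaf order and rerooting", {
  set.seed(87)
  tr <- ape::rtree(7)
  m <- matrix(sample(AA20, 7 * 15, replace = TRUE), 7, 15,
              dimnames = list(tr$tip.label, NULL))
  base <- site_rates(m, tr, alpha = 0.9)$loglik
  perm <- m[sample(rownames(m)), ]
  expect_equal(site_rates(perm, tr, alpha = 0.9)$loglik, base,
               tolerance = 1e-8)
  rerooted <- ape::unroot(tr)
  expect_equal(site_rates(m, rerooted, alpha = 0.9)$loglik, base,
               tolerance = 1e-8)
})

test_that("planted slow and fast site rates are recovered", {
  set.seed(88)
  tr <- ape::rtree(10)
  tr$edge.length <- tr$edge.length * 0.8
  tips <- tr$tip.label
  true_rates <- rep(c(0.25, 3), each = 30)
  anc <- seq_record("anc", random_peptide(60, AA19))
  fam <- evolve_family(anc, tr, true_rates, "rt")
  m <- do.call(rbind, lapply(fam$records, function(r) strsplit(r$residues, "")[[1]]))
  rownames(m) <- record_ids_for_test(fam$records)
  rownames(m) <- sub("rt_", "", rownames(m))
  m <- m[tips, ]
  sr <- site_rates(m, tr)
  expect_gte(cor(sr$rate, true_rates, method = "spearman"), 0.6)
})
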