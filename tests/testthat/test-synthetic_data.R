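test_that("sim_config validates its inputs", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, tandem_divergence = c(0.1, 1.3)))
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_families, 3)
})

test_that("scaffolds carry the pattern's cysteines within bounds", {
  cfg <- sim_config(seed = 101)
  set.seed(101)
  for (i in 1:50) {
    sc <- make_scaffold(cfg, sprintf("s%d", i))
    cys <- attr(sc, "cys_positions")
    expect_length(cys, 6)
    sp <- diff(cys) - 1
    expect_true(all(sp >= cfg$scaffold$loop_bounds[, 1] &
                    sp <= cfg$scaffold$loop_bounds[, 2]))
    # the attribute matches the sequence itself
    expect_equal(which(strsplit(sc$residues, "")[[1]] == "C"), cys)
  }
})

test_that("scaffold generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 102)
  a <- make_scaffold(cfg, "x", seed = 55)
  b <- make_scaffold(cfg, "x", seed = 55)
  expect_identical(a$residues, b$residues)
})

test_that("generated scaffolds are always accepted by scan_ick", {
  cfg <- sim_config(seed = 103)
  set.seed(103)
  for (i in 1:200) {
    sc <- make_scaffold(cfg, "s")
    hits <- scan_ick(sc, cfg$scaffold)
    expect_equal(nrow(hits), 1)
    cys <- attr(sc, "cys_positions")
    expect_equal(hits$start, cys[1])
    expect_equal(hits$end, cys[6])
  }
})

test_that("zero-length branches leave all leaves identical to the ancestor", {
  cfg <- sim_config(seed = 104)
  set.seed(104)
  anc <- make_scaffold(cfg, "anc")
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length * 0
  fam <- evolve_family(anc, tr,
                       rep(1, nchar(anc$residues)), "z")
  for (r in fam$records) expect_identical(r$residues, anc$residues)
})

test_that("per-branch change fractions match the sampling closed form", {
  # substitution events arrive with probability 1 - e^{-20/19 rt}; a hit
  # redraws uniformly over the 19 non-cysteine letters, so a non-cysteine
  # site shows a change with probability (18/19)(1 - e^{-20/19 rt})
  set.seed(105)
  L <- 1000
  anc <- seq_record("anc", random_peptide(L, AA19))
  for (t in c(0.1, 0.5)) {
    tr <- ape::read.tree(text = sprintf("(tip:%f,z:0);", t))
    frac <- mean(vapply(1:30, function(i) {
      fam <- evolve_family(anc, tr, rep(1, L), "e")
      tip <- Filter(function(r) r$id == "e_tip", fam$records)[[1]]
      mean(strsplit(tip$residues, "")[[1]] != strsplit(anc$residues, "")[[1]])
    }, numeric(1)))
    want <- (18 / 19) * (1 - exp(-20 / 19 * t))
    # 30 x 1000 Bernoulli draws: allow four standard errors
    tol <- 4 * sqrt(want * (1 - want) / (30 * L))
    expect_lt(abs(frac - want), tol)
  }
})

test_that("fast sites accumulate more changes than slow sites", {
  set.seed(106)
  L <- 400
  anc <- seq_record("anc", random_peptide(L, AA19))
  rates <- rep(c(0.3, 3), each = L / 2)
  tr <- ape::read.tree(text = "(tip:0.4,z:0);")
  wins <- vapply(1:50, function(i) {
    fam <- evolve_family(anc, tr, rates, "e")
    tip <- Filter(function(r) r$id == "e_tip", fam$records)[[1]]
    ch <- strsplit(tip$residues, "")[[1]] != strsplit(anc$residues, "")[[1]]
    sum(ch[(L / 2 + 1):L]) > sum(ch[1:(L / 2)])
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("a zero-divergence tandem is a perfect duplication", {
  cfg <- sim_config(seed = 107, tandem_divergence = c(0, 0))
  set.seed(107)
  anc <- make_scaffold(cfg, "anc")
  cys <- attr(anc, "cys_positions")
  dom <- seq_record("dom", substr(anc$residues, cys[1], cys[6]))
  td <- make_tandem(dom, cfg, id = "t0", linker_len = 4)
  calls <- detect_internal_repeats(td$record)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$identity, 100)
  hits <- scan_ick(td$record)
  sp <- split_domains(td$record, hits)
  expect_equal(sp$linkers$length, 4)
  expect_equal(td$truth$linker_length, 4)
})

test_that("an Xt3a-like tandem assembled from parts reproduces the fixture", {
  x <- xt3a_scaffold()
  d1 <- substr(x$residues, 14, 45)
  d2 <- substr(x$residues, 50, 80)
  rec <- tandem_from_parts("rebuilt",
                           ntail = substr(x$residues, 1, 13),
                           domain1 = d1,
                           linker = substr(x$residues, 46, 49),
                           domain2 = d2,
                           ctail = substr(x$residues, 81, 82))
  expect_identical(rec$residues, x$residues)
  expect_equal(attr(rec, "domain_intervals"),
               rbind(c(14L, 45L), c(50L, 80L)))
  expect_equal(attr(rec, "linker_length"), 4L)
})

test_that("decoys never match the ICK pattern and follow the length law", {
  cfg <- sim_config(seed = 108, n_decoys = 100)
  decoys <- make_decoys(cfg, seed = 108)
  for (d in decoys) expect_equal(nrow(scan_ick(d, cfg$scaffold)), 0)
  lens <- vapply(decoys, function(d) nchar(d$residues), integer(1))
  # Kolmogorov-Smirnov against the configured uniform length range
  ks <- suppressWarnings(stats::ks.test(
    lens, "punif", cfg$decoy_length_range[1] - 1, cfg$decoy_length_range[2]))
  expect_gt(ks$p.value, 0.01)
  # determinism
  again <- make_decoys(cfg, seed = 108)
  expect_identical(vapply(again, function(d) d$residues, character(1)),
                   vapply(decoys, function(d) d$residues, character(1)))
})

test_that("the truth manifest verifies against emitted records", {
  bm <- make_benchmark(sim_config(seed = 109, n_decoys = 20,
                                  family_size = 4, n_tandems = 2))
  expect_true(verify_manifest(bm$records, bm$truth))
  # corrupting a record is caught
  broken <- bm$records
  idx <- which(record_ids_for_test(broken) == "tandem01")
  res <- broken[[idx]]$residues
  cys1 <- which(strsplit(res, "")[[1]] == "C")[1]
  substr(res, cys1, cys1) <- "A"
  broken[[idx]]$residues <- res
  expect_error(verify_manifest(broken, bm$truth), "inconsistent")
})
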