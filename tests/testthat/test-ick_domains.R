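test_that("the Xt3a scaffold yields exactly its two known domains", {
  hits <- scan_ick(xt3a_scaffold())
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(14, 50))
  expect_equal(hits$end, c(45, 80))
  expect_equal(hits$ds_class, c("3DS", "3DS"))
  expect_equal(hits$cys_positions,
               c("14;21;28;29;34;45", "50;57;64;65;70;80"))
})

test_that("cysteine-free sequences produce zero hits", {
  set.seed(8)
  rec <- seq_record("nocys", random_peptide(300, AA19))
  expect_equal(nrow(scan_ick(rec)), 0)
})

test_that("scan_ick equals the exhaustive window oracle on fuzzed sequences", {
  set.seed(31)
  pat <- ick_pattern("3DS")
  for (i in 1:100) {
    # mix implanted scaffolds with random cysteine salt
    s <- if (i %% 2) {
      paste0(random_peptide(sample(0:30, 1), AA19), make_domain_string(),
             random_peptide(sample(0:20, 1)),
             if (i %% 4 == 1) make_domain_string(c(6, 6, 0, 4, 9)) else "",
             random_peptide(sample(0:10, 1)))
    } else {
      random_peptide(sample(40:400, 1),
                     c(AA19, rep("C", sample(1:6, 1))))
    }
    got <- scan_ick(seq_record("z", s), pat)
    want <- oracle_scan(s, pat$n_cys, pat$loop_bounds)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"))
      expect_equal(got$end, vapply(want, `[[`, numeric(1), "end"))
    }
  }
})

test_that("split_domains reproduces the Xt3a linker and spans", {
  x <- xt3a_scaffold()
  sp <- split_domains(x, scan_ick(x))
  expect_length(sp$domains, 2)
  expect_equal(sp$linkers$length, 4)
  expect_equal(sp$domains[[1]]$residues, substr(x$residues, 14, 45))
  expect_equal(sp$domains[[2]]$residues, substr(x$residues, 50, 80))
  # single hit: one record, no linkers
  one <- split_domains(x, scan_ick(x)[1, , drop = FALSE])
  expect_length(one$domains, 1)
  expect_equal(nrow(one$linkers), 0)
})

test_that("linker lengths equal construction gaps for implanted domains", {
  set.seed(12)
  for (rep in 1:10) {
    gaps <- sample(0:12, 2)
    s <- paste0(random_peptide(6, AA19),
                make_domain_string(), random_peptide(gaps[1], AA19),
                make_domain_string(), random_peptide(gaps[2], AA19),
                make_domain_string(), random_peptide(3, AA19))
    rec <- seq_record("tri", s)
    hits <- scan_ick(rec)
    expect_equal(nrow(hits), 3)
    sp <- split_domains(rec, hits)
    expect_equal(sp$linkers$length, gaps)
    # domain + linker + tail lengths tile the parent exactly
    total <- sum(vapply(sp$domains, function(d) nchar(d$residues), integer(1))) +
      sum(sp$linkers$length) + (hits$start[1] - 1) +
      (nchar(s) - hits$end[3])
    expect_equal(total, nchar(s))
  }
})

test_that("knottin connectivity follows the C1-C4/C2-C5/C3-C6 rule", {
  hits <- scan_ick(xt3a_scaffold())
  d1 <- predict_connectivity(hits[1, ])
  expect_equal(d1$pos_a, c(14, 21, 28))
  expect_equal(d1$pos_b, c(29, 34, 45))
  d2 <- predict_connectivity(hits[2, ])
  expect_equal(d2$pos_a, c(50, 57, 64))
  expect_equal(d2$pos_b, c(65, 70, 80))
  # each cysteine is used exactly once (perfect matching)
  expect_equal(sort(c(d1$pos_a, d1$pos_b)), c(14, 21, 28, 29, 34, 45))
  expect_equal(sort(c(d2$pos_a, d2$pos_b)), c(50, 57, 64, 65, 70, 80))
  # wrong cysteine count errors, naming the count
  bad <- data.frame(parent_id = "b", start = 1, end = 20, ds_class = "3DS",
                    cys_positions = "1;5;10;15;20")
  expect_error(predict_connectivity(bad), "5 cysteines")
})

test_that("the 4-DS rule pairs the extra loop-four disulfide", {
  hit <- data.frame(parent_id = "q", start = 1, end = 50, ds_class = "4DS",
                    cys_positions = "1;8;15;16;21;25;28;50")
  pairs <- predict_connectivity(hit)
  expect_equal(nrow(pairs), 4)
  expect_equal(pairs$pos_a, c(1, 8, 15, 25))
  expect_equal(pairs$pos_b, c(16, 21, 50, 28))
})

test_that("an exact duplication is called at 100% identity", {
  set.seed(77)
  u <- random_peptide(40, AA19)
  calls <- detect_internal_repeats(seq_record("dup", paste0(u, u)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$identity, 100)
  expect_equal(c(calls$start_a, calls$end_a, calls$start_b, calls$end_b),
               c(1, 40, 41, 80))
})

test_that("a random 100-aa sequence yields no repeat call at 60% identity", {
  # the brute-force self-alignment oracle confirms emptiness on this seed
  set.seed(2024)
  r100 <- random_peptide(100)
  expect_equal(nrow(detect_internal_repeats(seq_record("r", r100),
                                            min_identity = 60)), 0)
})

test_that("repeat calls agree with the brute-force self-alignment oracle", {
  set.seed(55)
  for (k in 1:40) {
    u <- random_peptide(sample(30:50, 1))
    u2 <- substitute_k(u, sample(3:22, 1))
    s <- paste0(random_peptide(sample(0:10, 1), AA19), u,
                random_peptide(sample(2:8, 1), AA19), u2,
                random_peptide(sample(0:6, 1), AA19))
    imp <- detect_internal_repeats(seq_record("x", s))
    ora <- oracle_repeat_calls(s)
    expect_equal(nrow(imp), length(ora))
    for (c in seq_len(nrow(imp))) {
      o <- ora[[c]]
      expect_equal(c(imp$start_a[c], imp$end_a[c]), unname(o$span_a))
      expect_equal(c(imp$start_b[c], imp$end_b[c]), unname(o$span_b))
      expect_equal(imp$identity[c], o$identity)
      expect_equal(imp$score[c], o$score)
    }
  }
})

test_that("repeat detection is mirror-symmetric under sequence reversal", {
  set.seed(60)
  for (k in 1:8) {
    u <- random_peptide(40)
    u2 <- substitute_k(u, 8)
    s <- paste0(random_peptide(5, AA19), u, random_peptide(4, AA19), u2)
    n <- nchar(s)
    fwd <- detect_internal_repeats(seq_record("f", s))
    rev <- detect_internal_repeats(
      seq_record("r", paste(rev(strsplit(s, "")[[1]]), collapse = "")))
    expect_equal(nrow(fwd), nrow(rev))
    if (nrow(fwd) == 1) {
      expect_equal(rev$start_a, n - fwd$end_b + 1)
      expect_equal(rev$end_b, n - fwd$start_a + 1)
      expect_equal(rev$identity, fwd$identity)
      expect_equal(rev$score, fwd$score)
    }
  }
})

test_that("qc_filter applies the documented reason codes", {
  # a domain with one 40-residue loop under max_loop 25 is removed
  long_loop <- seq_record("ll", make_domain_string(c(6, 6, 0, 4, 10)))
  ll_wide <- seq_record("llw", paste0(
    random_peptide(3, AA19),
    make_domain_string(c(6, 6, 0, 4, 40))))
  pat_wide <- ick_pattern("3DS", rbind(c(3, 9), c(3, 9), c(0, 7), c(1, 17),
                                       c(3, 45)))
  hits <- rbind(scan_ick(long_loop, pat_wide), scan_ick(ll_wide, pat_wide))
  qc <- qc_filter(list(long_loop, ll_wide), hits)
  expect_equal(qc$reason, c("OK", "LONG_LOOP"))
  # the Xt3a fixture is kept under defaults
  x <- xt3a_scaffold()
  expect_equal(qc_filter(list(x), scan_ick(x))$reason, "OK")
  # five cysteines where six are required
  five <- seq_record("five", paste0("C", strrep("A", 4), "C", strrep("A", 4),
                                    "C", strrep("A", 4), "C", strrep("A", 4),
                                    "C"))
  qc5 <- qc_filter(list(five), scan_ick(five))
  expect_equal(qc5$reason, "MISSING_CYS")
  expect_false(qc5$kept)
  # overlong N-terminus before the first domain cysteine
  nt <- seq_record("nt", paste0(random_peptide(70, AA19),
                                make_domain_string()))
  qn <- qc_filter(list(nt), scan_ick(nt))
  expect_equal(qn$reason, "LONG_NTERM")
})
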