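NON_CYS <- setdiff(AA_ALPHABET20, "C")

#' Configuration for the synthetic toxin-family generator
#'
#' Bundles every knob of the simulator with defaults that emulate the data
#' regime the pipeline is built for: a handful of ICK families with an
#' absolutely conserved cysteine scaffold and variable inter-cysteine loops,
#' a small set of tandem (double-knot) duplications whose second domain
#' diverges faster than the first, and a large background of non-ICK decoy
#' secreted peptides.
#'
#' @param seed Integer seed (mandatory).
#' @param n_families Number of single-domain ICK families (default 3).
#' @param family_size Leaves per family tree (default 12).
#' @param scaffold An [ick_pattern()] (default the packaged 3-DS pattern).
#' @param nterm_range,cterm_range Tail length ranges for scaffolds.
#' @param rate_slow,rate_fast,p_fast Per-site rate classes: each mutable
#'   site is fast with probability `p_fast` (defaults 0.3 / 3.0 / 0.3).
#' @param tree_depth Mean root-to-tip divergence of family trees in expected
#'   substitutions per site (default 0.3).
#' @param n_tandems Number of tandem duplications (default 5).
#' @param tandem_divergence Length-2 vector: per-domain divergence (expected
#'   substitutions per site) applied to the two copies (default c(0.1, 0.3),
#'   the faster second domain).
#' @param linker_range Tandem linker length range (default c(2, 10)).
#' @param n_decoys Number of decoys (default 200).
#' @param decoy_length_range Decoy length range (default c(60, 200)).
#' @param decoy_cys_freq Per-position cysteine probability in decoys
#'   (default 0.02).
#' @param max_attempts Rejection-sampling cap per decoy (default 100).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_families = 3L,
                       family_size = 12L,
                       scaffold = ick_pattern("3DS"),
                       nterm_range = c(5L, 15L),
                       cterm_range = c(1L, 6L),
                       rate_slow = 0.3,
                       rate_fast = 3,
                       p_fast = 0.3,
                       tree_depth = 0.3,
                       n_tandems = 5L,
                       tandem_divergence = c(0.1, 0.3),
                       linker_range = c(2L, 10L),
                       n_decoys = 200L,
                       decoy_length_range = c(60L, 200L),
                       decoy_cys_freq = 0.02,
                       max_attempts = 100L) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  stopifnot(inherits(scaffold, "ick_pattern"),
            all(tandem_divergence >= 0), all(tandem_divergence <= 1),
            all(linker_range >= 0), rate_slow > 0, rate_fast > 0,
            p_fast >= 0, p_fast <= 1, decoy_cys_freq >= 0,
            decoy_cys_freq < 1)
  structure(as.list(environment()), class = "sim_config")
}

sample_in_range <- function(range) {
  if (range[1] == range[2]) return(as.integer(range[1]))
  sample(seq.int(range[1], range[2]), 1L)
}

#' Generate one ICK scaffold sequence
#'
#' Places the pattern's cysteines with inter-cysteine spacings drawn
#' uniformly within the loop bounds, surrounded by N-/C-terminal tails;
#' every non-cysteine residue is i.i.d. uniform over the 19 non-cysteine
#' amino acids, so the cysteine signal is unambiguous ground truth.
#'
#' @param cfg A [sim_config()].
#' @param id Record id (default `"scaffold"`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A [seq_record()] with attribute `cys_positions`.
#' @export
make_scaffold <- function(cfg, id = "scaffold", seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  bounds <- cfg$scaffold$loop_bounds
  spacings <- vapply(seq_len(nrow(bounds)),
                     function(r) sample_in_range(bounds[r, ]), integer(1))
  nterm <- sample_in_range(cfg$nterm_range)
  cterm <- sample_in_range(cfg$cterm_range)
  cys <- nterm + 1L + c(0L, cumsum(spacings + 1L))
  len <- cys[length(cys)] + cterm
  res <- sample(NON_CYS, len, replace = TRUE)
  res[cys] <- "C"
  rec <- seq_record(id, paste(res, collapse = ""),
                    description = sprintf("synthetic %s scaffold",
                                          cfg$scaffold$ds_class),
                    source = "synthetic")
  attr(rec, "cys_positions") <- cys
  rec
}

# Poisson-clock substitution sampling: a site is hit by at least one event
# with probability 1 - e^{-20/19 r t} (the mean-one Poisson model's event
# probability); on an event the residue redraws uniformly from the 19
# non-cysteine letters, so cysteine ground truth stays unambiguous. For a
# non-cysteine parent the observed per-site change probability is therefore
# (18/19) (1 - e^{-20/19 r t}).
mutate_residues <- function(res, t, rates, protect) {
  n <- length(res)
  stopifnot(length(rates) == n)
  keep <- runif(n) < exp(-20 / 19 * rates * t)
  redraw <- which(!keep)
  redraw <- setdiff(redraw, protect)
  if (length(redraw) > 0) {
    res[redraw] <- sample(NON_CYS, length(redraw), replace = TRUE)
  }
  res
}

#' Draw a per-site rate profile for a scaffold
#'
#' Each mutable site is independently fast (rate `rate_fast`) with
#' probability `p_fast`, otherwise slow (`rate_slow`); cysteine positions
#' get rate 0 (absolute conservation).
#'
#' @param cfg A [sim_config()].
#' @param len Sequence length.
#' @param cys Cysteine positions.
#' @return Numeric rate vector of length `len`.
#' @export
draw_site_rates <- function(cfg, len, cys) {
  rates <- ifelse(runif(len) < cfg$p_fast, cfg$rate_fast, cfg$rate_slow)
  rates[cys] <- 0
  rates
}

#' Evolve a family of sequences along a tree
#'
#' Starting from the ancestor at the root, residues mutate along each branch
#' under the 20-state Poisson model with per-site probabilities scaled by
#' branch length times site rate; cysteine positions never mutate. Returns
#' the leaf records plus a ground-truth manifest.
#'
#' @param ancestor A [seq_record()] (e.g. from [make_scaffold()]).
#' @param tree A `phylo` tree with nonnegative branch lengths.
#' @param rates Numeric per-site rate vector (length = ancestor length).
#' @param family Family label stored in the manifest.
#' @param seed Optional seed.
#' @return List `records` (leaf [seq_record()]s named `<family>_<tip>`) and
#'   `truth` (list: `family`, `tree` newick, `site_rates`, `cys_positions`).
#' @export
evolve_family <- function(ancestor, tree, rates, family = "fam", seed = NULL) {
  stopifnot(inherits(ancestor, "seq_record"), inherits(tree, "phylo"),
            all(tree$edge.length >= 0))
  if (!is.null(seed)) set.seed(seed)
  cys <- cys_positions_of(ancestor$residues)
  res0 <- strsplit(ancestor$residues, "")[[1]]
  stopifnot(length(rates) == length(res0))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- res0
  # preorder: parents before children
  for (k in rev(ape::postorder(tree))) {
    parent <- tree$edge[k, 1]
    child <- tree$edge[k, 2]
    seqs[[child]] <- mutate_residues(seqs[[parent]], tree$edge.length[k],
                                     rates, cys)
  }
  records <- lapply(seq_len(ntip), function(i) {
    seq_record(sprintf("%s_%s", family, tree$tip.label[i]),
               paste(seqs[[i]], collapse = ""),
               description = sprintf("simulated member of %s", family),
               source = "synthetic")
  })
  list(records = records,
       truth = list(family = family, tree = ape::write.tree(tree),
                    site_rates = rates, cys_positions = cys))
}

#' Assemble a tandem (double-knot) record from explicit parts
#'
#' @param id Record id.
#' @param ntail,linker,ctail Residue strings ("" allowed).
#' @param domain1,domain2 Domain residue strings (cysteine-bounded).
#' @return A [seq_record()] with truth attributes `domain_intervals` (2 x 2
#'   matrix of start/end) and `linker_length`.
#' @export
tandem_from_parts <- function(id, ntail, domain1, linker, domain2, ctail) {
  res <- paste0(ntail, domain1, linker, domain2, ctail)
  d1_start <- nchar(ntail) + 1L
  d1_end <- d1_start + nchar(domain1) - 1L
  d2_start <- d1_end + nchar(linker) + 1L
  d2_end <- d2_start + nchar(domain2) - 1L
  rec <- seq_record(id, res, description = "synthetic tandem double-knot",
                    source = "synthetic")
  attr(rec, "domain_intervals") <- rbind(c(d1_start, d1_end),
                                         c(d2_start, d2_end))
  attr(rec, "linker_length") <- nchar(linker)
  rec
}

#' Simulate a tandem duplication of an ICK domain
#'
#' Emulates the double-knot architecture: N-tail + domain copy 1 + linker +
#' domain copy 2 + C-tail, where each copy of the ancestral domain diverges
#' independently by `cfg$tandem_divergence` expected substitutions per site
#' (cysteines protected), supporting domain-selective divergence.
#'
#' @param ancestor A [seq_record()] whose residues are one cysteine-bounded
#'   ICK domain (first and last residues are cysteines).
#' @param cfg A [sim_config()].
#' @param id Record id.
#' @param linker_len Linker length; `NULL` draws from `cfg$linker_range`.
#' @param seed Optional seed.
#' @return List `record` (a [seq_record()] with truth attributes as in
#'   [tandem_from_parts()]) and `truth` (list with intervals, linker length
#'   and per-domain divergence).
#' @export
make_tandem <- function(ancestor, cfg, id = "tandem", linker_len = NULL,
                        seed = NULL) {
  stopifnot(inherits(ancestor, "seq_record"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  dres <- strsplit(ancestor$residues, "")[[1]]
  cys <- cys_positions_of(ancestor$residues)
  stopifnot(length(cys) >= 2, cys[1] == 1L, cys[length(cys)] == length(dres))
  if (is.null(linker_len)) linker_len <- sample_in_range(cfg$linker_range)
  ones <- rep(1, length(dres))
  d1 <- mutate_residues(dres, cfg$tandem_divergence[1], ones, cys)
  d2 <- mutate_residues(dres, cfg$tandem_divergence[2], ones, cys)
  ntail <- paste(sample(NON_CYS, sample_in_range(cfg$nterm_range),
                        replace = TRUE), collapse = "")
  ctail <- paste(sample(NON_CYS, sample_in_range(cfg$cterm_range),
                        replace = TRUE), collapse = "")
  linker <- paste(sample(NON_CYS, linker_len, replace = TRUE), collapse = "")
  rec <- tandem_from_parts(id, ntail, paste(d1, collapse = ""), linker,
                           paste(d2, collapse = ""), ctail)
  list(record = rec,
       truth = list(id = id,
                    domain_intervals = attr(rec, "domain_intervals"),
                    linker_length = linker_len,
                    divergence = cfg$tandem_divergence))
}

#' Generate non-ICK decoy sequences
#'
#' Decoys draw their length from `cfg$decoy_length_range` and place a
#' cysteine at each position with probability `cfg$decoy_cys_freq`;
#' rejection sampling guarantees that no decoy matches the configured ICK
#' pattern.
#'
#' @param cfg A [sim_config()].
#' @param n Number of decoys (default `cfg$n_decoys`).
#' @param seed Optional seed.
#' @return List of [seq_record()]s.
#' @export
make_decoys <- function(cfg, n = cfg$n_decoys, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(cfg$max_attempts)) {
      len <- sample_in_range(cfg$decoy_length_range)
      res <- sample(NON_CYS, len, replace = TRUE)
      res[runif(len) < cfg$decoy_cys_freq] <- "C"
      rec <- seq_record(sprintf("decoy_%03d", i), paste(res, collapse = ""),
                        description = "synthetic non-ICK decoy",
                        source = "synthetic")
      if (nrow(scan_ick(rec, cfg$scaffold)) == 0) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("make_decoys: rejection failed after ", cfg$max_attempts,
           " attempts for decoy ", i)
    }
    out[[i]] <- rec
  }
  out
}

#' Generate the default benchmark dataset with its truth manifest
#'
#' Builds `n_families` single-domain ICK families evolved along random
#' trees, `n_tandems` tandem duplications, and `n_decoys` decoys, entirely
#' determined by `cfg$seed`. The truth manifest is verified against the
#' emitted records before returning.
#'
#' @param cfg A [sim_config()].
#' @return List `records` (all [seq_record()]s) and `truth` (per-record
#'   ground truth: family label, domain intervals, cysteine offsets,
#'   duplication flag, plus per-family trees and site rates).
#' @export
make_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  records <- list()
  truth <- list(families = list(), records = list())
  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("fam%02d", f)
    anc <- make_scaffold(cfg, id = paste0(fam, "_anc"))
    cys <- attr(anc, "cys_positions")
    rates <- draw_site_rates(cfg, nchar(anc$residues), cys)
    tree <- ape::rtree(cfg$family_size)
    tree$edge.length <- tree$edge.length * cfg$tree_depth /
      mean(ape::node.depth.edgelength(tree)[seq_len(cfg$family_size)])
    ev <- evolve_family(anc, tree, rates, family = fam)
    records <- c(records, ev$records)
    truth$families[[fam]] <- ev$truth
    for (r in ev$records) {
      truth$records[[r$id]] <- list(
        family = fam, duplicated = FALSE,
        cys_positions = cys,
        domain_intervals = rbind(c(cys[1], cys[length(cys)])))
    }
  }
  for (t in seq_len(cfg$n_tandems)) {
    anc <- make_scaffold(cfg, id = sprintf("tandem%02d_anc", t))
    cys <- attr(anc, "cys_positions")
    dom <- seq_record("dom", substr(anc$residues, cys[1], cys[length(cys)]),
                      source = "synthetic")
    td <- make_tandem(dom, cfg, id = sprintf("tandem%02d", t))
    records <- c(records, list(td$record))
    truth$records[[td$record$id]] <- list(
      family = "tandem", duplicated = TRUE,
      cys_positions = cys_positions_of(td$record$residues),
      domain_intervals = td$truth$domain_intervals,
      linker_length = td$truth$linker_length)
  }
  decoys <- make_decoys(cfg)
  records <- c(records, decoys)
  for (r in decoys) {
    truth$records[[r$id]] <- list(family = "decoy", duplicated = FALSE,
                                  cys_positions = cys_positions_of(r$residues),
                                  domain_intervals = NULL)
  }
  verify_manifest(records, truth)
  list(records = records, truth = truth)
}

#' Verify a truth manifest against emitted records
#'
#' Checks that every per-record claim (cysteine offsets, domain intervals
#' bounded by cysteines) is consistent with the record residues; called
#' automatically by [make_benchmark()].
#'
#' @param records List of [seq_record()]s.
#' @param truth Manifest as produced by [make_benchmark()].
#' @return `TRUE` invisibly; errors on the first inconsistency.
#' @export
verify_manifest <- function(records, truth) {
  ids <- record_ids(records)
  stopifnot(setequal(ids, names(truth$records)))
  for (r in records) {
    tr <- truth$records[[r$id]]
    if (!identical(as.integer(tr$cys_positions),
                   as.integer(cys_positions_of(r$residues)))) {
      stop("manifest cysteine positions inconsistent for ", r$id)
    }
    if (!is.null(tr$domain_intervals)) {
      res <- strsplit(r$residues, "")[[1]]
      for (d in seq_len(nrow(tr$domain_intervals))) {
        iv <- tr$domain_intervals[d, ]
        if (res[iv[1]] != "C" || res[iv[2]] != "C") {
          stop("manifest domain interval not cysteine-bounded for ", r$id)
        }
      }
    }
  }
  invisible(TRUE)
}
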