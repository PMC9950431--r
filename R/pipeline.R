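#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys passed through
#' `...` are rejected.
#'
#' @param input_fasta Path to a FASTA of candidate secreted peptides, or
#'   `NULL` to run on records passed directly.
#' @param records List of [seq_record()]s (used when `input_fasta` is NULL).
#' @param seed Integer seed used for every stochastic stage (default 1).
#' @param patterns List of [ick_pattern()]s to scan (default: packaged 3-DS).
#' @param max_loop,max_nterm QC thresholds (see [qc_filter()]).
#' @param detect_repeats Run tandem-repeat detection (default TRUE).
#' @param repeat_min_identity,repeat_min_unit_len,repeat_max_rounds
#'   Repeat-detection thresholds (see [detect_internal_repeats()]).
#' @param cluster_threshold Redundancy clustering identity (default 0.99).
#' @param run_phylogeny Build tree/bootstrap/site rates (default TRUE; needs
#'   >= 4 aligned domains).
#' @param bootstrap_reps Bootstrap replicates (default 1000).
#' @param collapse_below Bootstrap collapse threshold (default 50).
#' @param n_components Principal components to retain (default 3).
#' @param k_neighbors Neighbours to report (default 10).
#' @param query_id Query for the neighbour report; `NULL` uses the first
#'   aligned domain.
#' @param out_dir Output directory for stage artifacts; `NULL` keeps
#'   everything in memory.
#' @param ... Rejected; catches unknown keys.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(input_fasta = NULL, records = NULL, seed = 1L,
                            patterns = list(ick_pattern("3DS")),
                            max_loop = 25L, max_nterm = 60L,
                            detect_repeats = TRUE,
                            repeat_min_identity = 40,
                            repeat_min_unit_len = 20L,
                            repeat_max_rounds = 3L,
                            cluster_threshold = 0.99,
                            run_phylogeny = TRUE,
                            bootstrap_reps = 1000L,
                            collapse_below = 50,
                            n_components = 3L,
                            k_neighbors = 10L,
                            query_id = NULL,
                            out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  if (inherits(patterns, "ick_pattern")) patterns <- list(patterns)
  stopifnot(all(vapply(patterns, inherits, logical(1), "ick_pattern")),
            cluster_threshold > 0, cluster_threshold <= 1,
            bootstrap_reps >= 1, n_components >= 1, k_neighbors >= 1)
  cfg <- list(input_fasta = input_fasta, records = records, seed = seed,
              patterns = patterns, max_loop = max_loop,
              max_nterm = max_nterm, detect_repeats = detect_repeats,
              repeat_min_identity = repeat_min_identity,
              repeat_min_unit_len = repeat_min_unit_len,
              repeat_max_rounds = repeat_max_rounds,
              cluster_threshold = cluster_threshold,
              run_phylogeny = run_phylogeny,
              bootstrap_reps = bootstrap_reps,
              collapse_below = collapse_below,
              n_components = n_components, k_neighbors = k_neighbors,
              query_id = query_id, out_dir = out_dir)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  hashable <- cfg[setdiff(names(cfg), c("records", "out_dir"))]
  hashable$patterns <- lapply(cfg$patterns, function(p) {
    list(ds_class = p$ds_class, loop_bounds = as.vector(p$loop_bounds))
  })
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(hashable, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from YAML
#'
#' Keys map one-to-one onto [pipeline_config()] arguments; `patterns` may be
#' given as a list of `ds_class` strings.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$patterns)) {
    raw$patterns <- lapply(raw$patterns, ick_pattern)
  }
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full mining and evolution pipeline
#'
#' Executes the stages in order: read -> ICK scan -> QC -> domain split (+
#' linker reports) -> tandem-repeat detection -> redundancy clustering ->
#' cysteine-anchored regional alignment -> NJ tree with bootstrap supports ->
#' site rates -> biophysical PCA sequence space with a neighbour report.
#' Stage outputs are written under `cfg$out_dir` when given; re-running with
#' an identical configuration and seed is byte-identical.
#'
#' @param cfg A `run_config` from [pipeline_config()].
#' @return List of class `run_result`: stage outputs plus `manifest`
#'   (tool version, config hash, per-stage counts, output checksums).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  records <- if (!is.null(cfg$input_fasta)) {
    read_fasta(cfg$input_fasta)
  } else if (!is.null(cfg$records)) {
    cfg$records
  } else {
    stop("run_pipeline: provide input_fasta or records")
  }
  check_unique_ids(records)

  hits <- do.call(rbind, c(
    list(data.frame(parent_id = character(), start = integer(),
                    end = integer(), ds_class = character(),
                    cys_positions = character(), stringsAsFactors = FALSE)),
    lapply(records, scan_ick, patterns = cfg$patterns)))
  required_cys <- min(vapply(cfg$patterns, function(p) p$n_cys, integer(1)))
  qc <- if (length(records) > 0) {
    qc_filter(records, hits, max_loop = cfg$max_loop,
              max_nterm = cfg$max_nterm, required_cys = required_cys)
  } else {
    data.frame(id = character(), kept = logical(), reason = character(),
               stringsAsFactors = FALSE)
  }
  kept_ids <- qc$id[qc$kept]
  kept <- records[record_ids(records) %in% kept_ids]

  domains <- list()
  linkers <- data.frame(upstream = character(), downstream = character(),
                        length = integer(), stringsAsFactors = FALSE)
  for (r in kept) {
    sp <- split_domains(r, hits[hits$parent_id == r$id, , drop = FALSE])
    domains <- c(domains, sp$domains)
    linkers <- rbind(linkers, sp$linkers)
  }

  repeats <- data.frame(parent_id = character(), start_a = integer(),
                        end_a = integer(), start_b = integer(),
                        end_b = integer(), identity = numeric(),
                        score = numeric(), stringsAsFactors = FALSE)
  if (cfg$detect_repeats) {
    for (r in kept) {
      repeats <- rbind(repeats, detect_internal_repeats(
        r, min_identity = cfg$repeat_min_identity,
        min_unit_len = cfg$repeat_min_unit_len,
        max_rounds = cfg$repeat_max_rounds))
    }
  }

  clusters <- greedy_cluster(domains, threshold = cfg$cluster_threshold)
  reps <- cluster_representatives(domains, clusters)

  aln <- NULL
  tree <- NULL
  rates <- NULL
  pca <- NULL
  neighbors <- NULL
  if (length(reps) >= 2) {
    counts <- vapply(reps, function(r) length(cys_positions_of(r$residues)),
                     integer(1))
    modal <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
    anchors <- anchor_cysteines(reps, k = modal)
    if (length(anchors$records) >= 2) {
      aln <- align_regions(anchors)
      if (cfg$run_phylogeny && length(anchors$records) >= 4) {
        tree <- bootstrap_support(aln, n_reps = cfg$bootstrap_reps,
                                  seed = cfg$seed,
                                  collapse_below = cfg$collapse_below)
        rates <- site_rates(aln, nj_tree(protein_distance(aln,
                                                          on_empty = "cap")))
      }
      feats <- featurize(aln)
      pca <- pca_project(feats, n_components = cfg$n_components)
      query <- if (!is.null(cfg$query_id)) cfg$query_id else aln$ids[1]
      if (query %in% aln$ids && length(aln$ids) >= 2) {
        neighbors <- nearest_neighbors(pca, query, k = cfg$k_neighbors)
      }
    }
  }

  manifest <- list(
    tool = "knotminer",
    version = as.character(utils::packageVersion("knotminer")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    counts = list(
      records_in = length(records),
      kept = sum(qc$kept),
      removed = as.list(table(qc$reason[!qc$kept])),
      domains = length(domains),
      domains_by_class = as.list(table(hits$ds_class)),
      repeat_calls = nrow(repeats),
      clusters = length(unique(clusters$representative)),
      aligned = if (is.null(aln)) 0L else length(aln$ids)
    ),
    elapsed_s = NULL # filled after outputs are written
  )

  result <- structure(list(records = records, hits = hits, qc = qc,
                           domains = domains, linkers = linkers,
                           repeats = repeats, clusters = clusters,
                           alignment = aln, tree = tree, site_rates = rates,
                           pca = pca, neighbors = neighbors,
                           manifest = manifest),
                      class = "run_result")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    p <- function(f) file.path(cfg$out_dir, f)
    paths <- c(paths, write_tsv(hits, p("hits.tsv")),
               write_tsv(qc, p("qc.tsv")),
               write_tsv(linkers, p("linkers.tsv")),
               write_tsv(repeats, p("repeats.tsv")),
               write_tsv(clusters, p("clusters.tsv")))
    if (length(domains) > 0) {
      paths <- c(paths, write_fasta(domains, p("domains.faa")))
    }
    if (!is.null(aln)) {
      paths <- c(paths, write_alignment_fasta(aln, p("alignment.faa")))
    }
    if (!is.null(tree)) {
      ape::write.tree(tree, p("tree.nwk"))
      paths <- c(paths, p("tree.nwk"))
    }
    if (!is.null(rates)) {
      paths <- c(paths, write_tsv(
        data.frame(column = seq_along(rates$rate), rate = rates$rate,
                   scored = rates$scored), p("site_rates.tsv")))
    }
    if (!is.null(pca)) {
      sc <- data.frame(id = rownames(pca$scores), pca$scores)
      paths <- c(paths, write_tsv(sc, p("pca_scores.tsv")))
    }
    if (!is.null(neighbors)) {
      paths <- c(paths, write_tsv(neighbors, p("neighbors.tsv")))
    }
    result$manifest$checksums <- as.list(tools::md5sum(sort(paths)))
    result$manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    jsonlite::write_json(result$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  } else {
    result$manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  result
}

#' Human-readable summary of a pipeline run
#'
#' @param result A `run_result` from [run_pipeline()].
#' @return Character vector of summary lines, invisibly; printed to the
#'   console.
#' @export
report <- function(result) {
  stopifnot(inherits(result, "run_result"))
  cn <- result$manifest$counts
  lines <- c(
    sprintf("knotminer run (config %s)", result$manifest$config_hash),
    sprintf("  records in:      %d", cn$records_in),
    sprintf("  kept after QC:   %d%s", cn$kept,
            if (length(cn$removed) > 0) {
              paste0(" (removed: ",
                     paste(sprintf("%s=%d", names(cn$removed),
                                   unlist(cn$removed)), collapse = ", "), ")")
            } else ""),
    sprintf("  ICK domains:     %d%s", cn$domains,
            if (length(cn$domains_by_class) > 0) {
              paste0(" (", paste(sprintf("%s=%d", names(cn$domains_by_class),
                                         unlist(cn$domains_by_class)),
                                 collapse = ", "), ")")
            } else ""),
    sprintf("  repeat calls:    %d", cn$repeat_calls),
    sprintf("  clusters:        %d", cn$clusters),
    sprintf("  aligned domains: %d", cn$aligned))
  if (!is.null(result$tree)) {
    lines <- c(lines, sprintf("  tree: %s", ape::write.tree(result$tree)))
  }
  if (!is.null(result$neighbors)) {
    lines <- c(lines,
               sprintf("  top neighbours of %s: %s",
                       attr(result$neighbors, "query"),
                       paste(result$neighbors$id, collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.run_result <- function(x, ...) {
  report(x)
  invisible(x)
}
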