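# knotminer

Desk-scale mining and evolutionary analysis of **inhibitor cystine knot
(ICK) peptides**, built around the tandem-repeat ("double-knot") toxin
architecture exemplified by the 82-residue remipede toxin Xt3a.

Venom peptides with the ICK fold — an anti-parallel β-sheet locked by three
disulfides in the knottin pseudo-knot C1–C4, C2–C5, C3–C6 — occasionally
duplicate into two-domain tandem toxins whose bivalent receptor engagement
confers extreme avidity. Identifying such peptides computationally takes a
chain of small analyses: recognise ICK domains from their cysteine
scaffold, find intra-sequence repeats, split and curate domains, align them
with the cysteines held in register, estimate their phylogeny and
per-column substitution rates, and ask which known toxin family each domain
resembles in biophysical "sequence space". `knotminer` packages that chain
for R users working at desk scale (hundreds to a few thousand candidate
sequences), together with a synthetic toxin-family generator so every stage
is testable without external databases.

## What it computes

* **Domain scan** — windows of 6 (3-DS) or 8 (4-DS) consecutive cysteines
  whose inter-cysteine spacings fall within configurable loop bounds;
  greedy leftmost tiling; QC with explicit reason codes.
* **Knottin connectivity** — rule-based disulfide pairing C1–C4, C2–C5,
  C3–C6 (plus C6–C7 for the 4-DS extra loop-four bond).
* **Tandem repeats** — optimal local self-alignment (BLOSUM62, affine gaps
  11 + L) with the band |i−j| < 20 excluded; iterative masking; calls carry
  spans, identity and score.
* **Redundancy clustering** — greedy 99% identity, CD-HIT-style
  shorter-sequence denominator.
* **Regional alignment** — conserved cysteines fixed as anchor columns;
  pre-/inter-/post-cysteine regions aligned independently by progressive
  profile alignment; Clustal-style conservation line.
* **Phylogeny & rates** — Kimura-corrected protein distances
  d = −ln(1 − p − 0.2p²), neighbour joining, nonparametric bootstrap with
  <50% branches collapsed; per-column discrete-gamma rates by Felsenstein
  pruning under a Poisson amino-acid model, normalised to mean 1.
* **Sequence space** — six descriptors per alignment cell (molecular
  weight, net charge, Kyte–Doolittle hydropathy, TOP-IDP disorder,
  disulfide potential, occupancy), PCA projection, ranked physicochemical
  neighbours.
* **Synthetic data** — ICK families evolved along trees, tandem
  duplications with domain-selective divergence, non-ICK decoys; every
  record backed by a verified ground-truth manifest.

## Worked example: the Xt3a scaffold

The package ships a fixture realising the twelve Xt3a cysteine positions
(synthetic filler elsewhere — scaffold analyses depend only on the
cysteines):

```r
library(knotminer)
x <- xt3a_scaffold()
(hits <- scan_ick(x))
#>       parent_id start end ds_class     cys_positions
#> 1 Xt3a_scaffold    14  45      3DS 14;21;28;29;34;45
#> 2 Xt3a_scaffold    50  80      3DS 50;57;64;65;70;80
```

Two independently folded 3-disulfide domains. Splitting them reports the
inter-domain linker — the four residues between Cys45 and Cys50:

```r
split_domains(x, hits)$linkers
#>           upstream       downstream length
#> 1 Xt3a_scaffold|D1 Xt3a_scaffold|D2      4
predict_connectivity(hits[1, ])
#>   pos_a pos_b rank
#> 1    14    29    1
#> 2    21    34    2
#> 3    28    45    3
```

The predicted knottin pairing of domain 1 (Cys14–Cys29, Cys21–Cys34,
Cys28–Cys45) matches the experimentally determined connectivity.

A full synthetic run — 3 families × 12 members, 5 tandem duplications, 200
decoys — goes through the whole pipeline in a few seconds:

```r
bm  <- make_benchmark(sim_config(seed = 11))
res <- run_pipeline(pipeline_config(records = bm$records, seed = 3,
                                    bootstrap_reps = 200))
report(res)
#> knotminer run (config 0f7bef72ad8c46c28ad4e81ddc665f7c)
#>   records in:      241
#>   kept after QC:   41 (removed: LONG_LOOP=17, MISSING_CYS=183)
#>   ICK domains:     46 (3DS=46)
#>   repeat calls:    5
#>   clusters:        46
#>   aligned domains: 46
```

All 41 ICK-bearing records survive QC, all 200 decoys are removed, the 46
true domains (36 single + 2 × 5 tandem) are found, and all five tandem
duplications are called by repeat detection.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic study set + truth manifest
Rscript analysis/02_scan_domains.R    # ICK scan, QC, split, connectivity, repeats
Rscript analysis/03_cluster_align.R   # 99% clustering, regional alignment
Rscript analysis/04_phylogeny_rates.R # NJ + bootstrap, site rates, D1-vs-D2 contrast
Rscript analysis/05_seqspace.R        # biophysical PCA, neighbour reports
```

Stage 4 prints the domain-selective evolution contrast (mean column rate of
the tandems' second domains vs their first), and stage 5 the top-10
physicochemical neighbours of a tandem's two domains.

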