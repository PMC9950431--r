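---
title: "Mining and evolutionary analysis of double-knot ICK peptides"
author: "knotminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and evolutionary analysis of double-knot ICK peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotminer)
```

## The problem

The inhibitor cystine knot (ICK, "knottin") is a compact peptide fold — an
anti-parallel β-sheet stabilised by three disulfides in a pseudo-knot
(C1–C4, C2–C5, C3–C6) — that dominates venom pharmacology because its
scaffold tolerates extreme sequence variation between the cysteines. A small
number of venom peptides carry *two* ICK domains in tandem, joined by a
short linker; such double-knot toxins can engage two receptor sites at once
and gain dramatic avidity. The remipede toxin Xt3a is the reference case
handled throughout this package: an 82-residue peptide with twelve
cysteines (positions 14, 21, 28, 29, 34, 45, 50, 57, 64, 65, 70, 80) that
form two three-disulfide knottin domains connected by a four-residue linker.

`knotminer` implements the computational side of characterising such
peptides at desk scale: find ICK domains in candidate secreted-peptide sets
by their cysteine spacing, locate intra-sequence tandem repeats, split
multi-domain sequences, remove redundancy, build a cysteine-anchored
multiple alignment, estimate a phylogeny with bootstrap support and
per-column substitution rates, and embed the domains in a biophysical
"sequence space" where physicochemical similarity is Euclidean distance.
Because the original inputs are large external databases, a synthetic-data
module generates toxin families with known ground truth so every stage is
testable offline.

## Domain detection by cysteine spacing

A candidate ICK domain is a window of `n_cys` consecutive cysteines (6 for
the 3-disulfide form, 8 for the 4-disulfide form) whose successive
inter-cysteine spacings each lie inside configurable `(min, max)` bounds.
The packaged 3-DS bounds — (3,9), (3,9), (0,7), (1,17), (3,19) residues —
were chosen to admit the Xt3a domains (spacings 6,6,0,4,10 and 6,6,0,4,9)
and typical calcin-like scaffolds while excluding loose cysteine salt; they
are parameters, not constants, because published pattern definitions vary.
Overlapping candidate windows are resolved greedily leftmost-first:
deterministic, and it tiles tandem domains the way they occur in the
sequence. The 4-DS default adds two short bounds for the extra loop-four
disulfide.

Disulfide connectivity is predicted by rule on the sorted cysteines of a
hit: C1–C4, C2–C5, C3–C6 for 3-DS. For 4-DS the core pairs are C1–C4,
C2–C5, C3–C8 with the additional pair C6–C7 closing loop four; the placement
of the extra pair is a declared convention (the extra disulfide is usually
described only as stabilising loop four), kept explicit in code so it can
be swapped.

Quality control mirrors the curation a practitioner applies before
alignment: hits with any inter-cysteine loop over `max_loop` (default 25
residues) are removed as `LONG_LOOP`; sequences whose first domain cysteine
sits more than `max_nterm` (default 60) residues from the N-terminus are
removed as `LONG_NTERM`; sequences that cannot supply the required cysteine
count are `MISSING_CYS`. The defaults are deliberately generous — they keep
every scaffold the generator can emit while excluding the degenerate
classes described above.

## Tandem-repeat detection by banded self-alignment

Internal repeats are found by aligning a sequence against itself with
Smith–Waterman local alignment under BLOSUM62 and affine gaps (a gap of
length L costs 11 + L), with the near-diagonal band `|i − j| <
min_unit_len` excluded so the trivial self-match is unreachable. The best
off-diagonal alignment is accepted as a repeat call when its identity
(identical columns over all alignment columns, gaps included) reaches
`min_identity` (default 40%), both projected intervals reach
`min_unit_len` (default 20 residues, also the excluded band width), and the
intervals do not overlap; the intervals are then masked and the search
iterates, up to `max_rounds` (default 3) calls.

One numerical subtlety matters in practice. When the linker between two
true repeat units is short, the *optimal* local alignment frequently
extends a few columns past the unit boundary — the path picks up a couple
of chance matches — so its raw projected intervals overlap by one to a few
residues. Rejecting those alignments outright discards genuine tandem
repeats (in our simulations roughly one duplication in fifteen). The
implementation therefore first trims such an alignment to its
best-scoring contiguous sub-path whose intervals do not overlap
(recomputing affine gap costs inside the window; ties broken toward longer
windows, then smaller start) and applies the acceptance criteria to the
trimmed alignment. Emitted intervals therefore never overlap, and
marginally overhanging alignments of real duplications are retained. The
core dynamic program is compiled (Rcpp); the test suite checks it against
an independent pure-R implementation of the same declared algorithm,
including a brute-force window search for the trimming step.

## Redundancy clustering

Before alignment and phylogeny, near-identical records are collapsed by
greedy clustering at 99% identity. Records are processed in a fixed order
(decreasing length, then lexicographic id); each joins the first cluster
whose representative it matches, else founds one. Identity is the number of
identical aligned positions of a global BLOSUM62 alignment divided by the
*shorter* sequence's length — the CD-HIT convention — so representatives
are never shorter than members and the output is invariant to input order.
No k-mer prefilter is used: all-vs-representative alignment is quadratic
and perfectly adequate below a few thousand records, which is the scale
this package targets.

## Cysteine-anchored regional alignment

ICK domains are alignable almost entirely through their conserved
cysteines; inter-cysteine loops are short, hypervariable, and often of
different lengths. The regional aligner therefore fixes the k cysteines of
each domain as single-residue anchor columns and aligns the k+1 pre-,
inter-, and post-cysteine regions independently, by progressive profile
alignment: guide order from 2-mer count distances (average-linkage
clustering, ties broken by lexicographic id), profile–profile global
alignment under BLOSUM62 with affine gaps, column scores averaged over
non-gap residue pairs. Regions whose width never exceeds one residue are
copied verbatim. Two invariants are enforced and fuzz-tested: anchor
columns are gap-free and all-cysteine, and degapping any row reproduces its
input sequence exactly. The per-region aligner is intentionally simple —
progressive with a fixed guide, no iterative refinement — because regions
are short and anchored at both ends; it is a self-contained component with
configurable scoring.

A Clustal-style conservation line summarises each column: `*` for a
gap-free single-residue column, `:` for a gap-free column within one strong
group (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW), `.` for a weak
group (CSA, ATV, SAG, STNK, STPA, SGND, SNDEQK, NDEQHK, NEQHRK, FVLIM,
HFY); any gap yields a space.

## Distance phylogeny, bootstrap, site rates

Pairwise distances are p-distances over mutually ungapped columns with
Kimura's empirical protein correction d = −ln(1 − p − 0.2p²); pairs near
saturation (log argument ≤ 0.01) are capped at −ln(0.01) ≈ 4.6
substitutions per site. Trees are Saitou–Nei neighbour joining (via
`ape::nj`, taxa presorted by id so ties resolve deterministically) with
negative branch lengths clamped to zero. Support comes from a nonparametric
bootstrap: columns resampled with replacement, one NJ tree per replicate,
each internal edge of the point tree scored by the percentage of replicate
trees containing its bipartition; edges below 50% support are collapsed
into multifurcations, the same convention used when such trees are drawn.
The default of 1,000 replicates is a deliberate desk-scale stand-in for the
much larger ultrafast-bootstrap runs used with maximum-likelihood trees;
distance-NJ plus nonparametric bootstrap replaces ML tree search entirely
in this package, which is the main declared methodological substitution.
During bootstrap, replicate pairs that lose all shared columns fall back to
the capped maximum distance rather than erroring, so every replicate yields
a tree.

Per-column substitution rates are estimated on a fixed tree by Felsenstein
pruning under a Poisson amino-acid model — uniform exchangeabilities and
frequencies, scaled to one expected substitution per unit branch length, so
P(same) = (1 + 19e^{−20/19·rt})/20 in closed form — across `n_categories`
(default 4) discrete-gamma rate categories (mean-of-bin discretisation).
The gamma shape α is optimised by bounded one-dimensional maximisation of
the total log-likelihood (interval 0.05–50) unless supplied. Each scored
column's rate is its posterior-mean category rate, normalised to mean 1
over scored columns; all-gap columns are flagged unscored. The Poisson
model was chosen over an empirical matrix because every quantity it
produces has a closed form the tests can pin to 10⁻¹⁰ (the two-taxon column
likelihood in particular); the model is pluggable where more realism is
wanted.

## Biophysical sequence space

Each alignment cell expands into six descriptors: molecular weight (Da,
free amino acid), integer net charge at pH 7 (K,R = +1; D,E = −1; H = 0 — a
declared convention, configurable, since published charge scales differ),
Kyte–Doolittle hydropathy, TOP-IDP disorder propensity, disulfide potential
(1 for cysteine), and occupancy (1 for a residue, 0 for a gap). Gaps
contribute zeros throughout; unknown residues (X) contribute occupancy only,
with a warning. The table ships as a versioned CSV. The feature matrix is
centered and unit-scaled (constant columns dropped and recorded), projected
by PCA, and signs fixed so each component's largest-magnitude loading is
positive. Neighbour reports rank Euclidean distances in the retained
three-component score space by default — matching the three-dimensional
projection this analysis style uses — with a `"full"` option because
"physicochemically most similar" is ambiguous about dimensionality; ties
break by id and the query is excluded.

## The synthetic-data generator

The generator produces the statistical structure the analysis assumes,
with a ground-truth manifest verified against the emitted sequences:

* **Scaffolds**: cysteines placed with spacings uniform within the pattern
  bounds; every non-cysteine residue i.i.d. uniform over the 19
  non-cysteine amino acids, so cysteine ground truth is unambiguous.
* **Families** (default 3 × 12 members): a scaffold ancestor evolved along
  a random tree (mean root-to-tip depth 0.3 expected substitutions per
  site) with two per-site rate classes (slow 0.3, fast 3.0, fast with
  probability 0.3). Substitution events arrive with the Poisson-model
  probability 1 − e^{−20/19·rt}; an event redraws the residue uniformly
  from the 19 non-cysteine letters, so a non-cysteine site shows an
  observed change with probability (18/19)(1 − e^{−20/19·rt}) — the closed
  form the tests assert. Cysteine positions never mutate.
* **Tandems** (default 5): N-tail + domain copy 1 + linker (2–10 residues)
  + domain copy 2 + C-tail, the two copies independently diverged by 0.1
  and 0.3 expected substitutions per site — the second domain evolves
  faster, which the rate-estimation stage must recover.
* **Decoys** (default 200, lengths 60–200): cysteines at 2% per position,
  rejection-sampled so no decoy matches the ICK pattern.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: insertion/deletion events inside loops (divergence
is purely substitutional; real loop length variation enters only through
scaffold sampling), signal peptides and propeptides, compositional bias
(real venom peptides are not uniform over 19 letters), correlated rate
variation along branches, and homoplasy from convergent loops. The
benchmark demonstrates that the machinery is correct under its own model,
not that the thresholds are optimal for any particular transcriptome.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed and is byte-identical under
it. The test suite exercises the oracles at these sizes, chosen to keep a
full run in a few minutes on one CPU: 500 fuzzed sequences for the domain
scanner against an exhaustive window oracle; 200 simulated duplications at
50–90% unit identity against the brute-force self-alignment oracle; 1,000
fuzzed families for alignment invariants; 100 random additive matrices
(≤ 12 taxa) for NJ exactness; a 10-taxon/60-column benchmark for site-rate
recovery (Spearman ≥ 0.6); 20 replicates of the domain-selective-divergence
contrast; and 100 replicates of planted-cluster neighbour recovery.

## Known limitations

The NJ + nonparametric bootstrap stand-in can differ from ML trees for
deep or rate-heterogeneous divergences; the Poisson rate model compresses
rate contrasts relative to empirical-matrix ML estimates (recovery is
monotone, hence the rank-correlation criterion); the regional aligner
assumes the anchor cysteine count is exactly k and rejects deviants rather
than re-aligning them; and the greedy cluster representative choice is
order-dependent by design (longest-first), which matches CD-HIT but is not
a globally optimal clustering.
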