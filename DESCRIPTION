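Package: knotminer
Title: Mining and Evolutionary Analysis of Inhibitor Cystine Knot Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and characterising
    tandem-repeat inhibitor cystine knot (ICK) venom peptides. Detects ICK
    domains in secreted-peptide sets by canonical cysteine spacing patterns,
    finds internal tandem repeats by exact local self-alignment, predicts
    knottin disulfide connectivity, removes redundancy by greedy identity
    clustering, builds cysteine-anchored regional multiple alignments,
    estimates distance-based phylogenies with bootstrap support and
    per-column substitution rates, and embeds aligned domains in a
    physicochemical principal-component sequence space with ranked
    neighbour reports. Includes a synthetic toxin-family generator with
    ground-truth manifests so every stage is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
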