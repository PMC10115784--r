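Package: allorigin
Title: Subgenome-Aware Inference of Reticulate Allopolyploid Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to discriminate a reticulate-allopolyploidization origin
    from a nested whole-genome-duplication origin for polyploid genomes.
    Provides a synthetic-genome simulator with known evolutionary truth
    (subgenome labels, homoeologous exchanges, LTR retrotransposon insertion
    ages, divergence times), orthogroup construction and collinear-block
    chaining for anchor-gene extraction at exact copy ratios, distance-based
    gene and species tree inference with bootstrap and quartet-score
    summaries, a rooted-topology census against competing polyploidy models,
    k-mer based subgenome phasing with window-level enrichment tests and
    homoeologous-exchange calling, read-composition profiling, and molecular
    dating from LTR terminal-repeat divergence and synonymous-substitution
    (Ks) ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    data.table,
    ape,
    phangorn,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
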