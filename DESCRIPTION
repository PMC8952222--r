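Package: coevscreen
Title: Inter-Protein Coevolution Screening from Orthologue Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens pairs of proteins for coevolving residue pairs from
    per-protein orthologue alignments. For every unordered protein pair the
    alignments are restricted to the shared species, per-site evolutionary
    variation is scored from BLOSUM-weighted residue transitions normalized
    by patristic divergence time, and inter-protein site pairs are ranked by
    Pearson correlation of their variation vectors. Significance is assessed
    against an empirical column-pair null with permutation p-values,
    bootstrap support, a bidirectional double run, Benjamini-Hochberg false
    discovery control, and a per-pair chi-squared enrichment test. Includes
    neighbour-joining tree construction with minimum-height rooting,
    alignment column-quality classification, orthologue curation by global
    alignment, a sequence evolution simulator with injectable correlated
    site pairs for benchmarking, and Cytoscape-ready network export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phytools,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
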