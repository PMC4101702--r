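Package: panar
Title: Pathway Network Inference from Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers pathway-interaction networks from gene expression
    matrices. Each pathway's expression submatrix is compressed into a
    small number of significant pathway profiles by principal component
    analysis with a bootstrap gamma-distribution eigenvalue cutoff;
    direct and opposite association rules between profiles are then
    extracted with an entropy-based adaptive discretization and scored
    by sensitivity and specificity; per-profile driving genes are
    identified by a kernel-density loading cutoff; and inferred networks
    can be validated against gene-pair association-score tables. A
    factorial simulation generator for benchmarking is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
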