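Package: napcensus
Title: Homogeneity Census and Network Audit for Network-Pharmacology Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a field-level census of the key metabolites, targets and
    pathways reported by network-analysis (network pharmacology) studies of
    natural products. Reads structured per-study extraction corpora, matches
    finding-list headings against a priori glossaries, standardizes element
    nomenclature through synonym maps, builds per-category eligibility cohorts
    with full exclusion ledgers, and computes prevalence rankings with
    threshold-sensitivity, methodology-stratified and chemical-class-share
    analyses. Includes a compound-target bipartite network audit that flags
    "chemical ghost" compounds lacking in-vivo detection evidence, measures
    their degree inflation and identifies ghost-only targets, plus a synthetic
    corpus generator with a popularity-biased (Zipf-like) element model and an
    exact analytic inclusion-probability oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
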