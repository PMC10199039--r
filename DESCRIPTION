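Package: lorescan
Title: Detecting Shared Whole-Genome Duplication Masked by Lineage-Specific
    Rediploidization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer whether two sister lineages share an ancient
    whole-genome duplication (WGD) that is masked by asynchronous,
    lineage-specific rediploidization. Gene family trees containing an
    ohnolog pair in each of two focal species are rooted, checked for
    monophyly of the focal quartet, reconciled against a species tree, and
    classified by the position of the duplication node relative to
    speciation (PreSpec, PostSpec, or near-miss 'Other' topologies). The
    classification is validated with approximately unbiased (AU) topology
    tests via multiscale RELL bootstrap, branch-support filtering with fold
    deviations from a uniform-topology null, clade-recovery checks, and
    alignment/tree diagnostics. Corroborating evidence is assembled from
    synonymous-distance (Ks) distributions (NG86 estimator), chromosomal
    synteny stratification of topology categories, and read-depth detection
    of collapsed duplicate regions. A synthetic-data generator simulates
    WGD plus block-wise rediploidization scenarios with ground truth so the
    whole pipeline is testable end to end, and a supermatrix builder
    prepares randomly A/B-assigned ohnolog concatenations for downstream
    phylogenomic dating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
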