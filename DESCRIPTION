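Package: lncFFLnet
Title: Dysregulated lncRNA-Mediated Feedforward Loops from Case/Control
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds lncRNA-mediated feedforward loop (lnc-FFL) networks from
    typed molecular interaction edge lists (gene-miRNA, gene-lncRNA,
    miRNA-lncRNA), scores every loop for dysregulation between two sample
    groups by combining per-molecule differential expression (Student t-test
    p-value products) with differential co-expression (absolute products of
    Pearson correlation differences), aggregates the two composite scores by
    equal-weighted ranking, and assigns significance by sample-label
    permutation. Downstream utilities extract gene-set subnetworks, key
    (hub) and core (dense-region, ClusterONE-style) modules, merge loops
    with competing endogenous RNA triplets into complex modules, and overlay
    drug-target associations for repurposing candidate screens. A synthetic
    data generator plants dysregulated loops in matched case/control
    expression bundles so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'aaa-utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'network-builder.R'
    'expression-io.R'
    'scoring.R'
    'genesets.R'
    'modules.R'
    'drugs.R'
    'synthetic.R'
    'pipeline.R'
    'lncFFLnet-package.R'
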