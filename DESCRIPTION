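Package: pathcorr
Title: Time-Series Multi-Omics Correlation Mapping for Cell Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates time-series metabolite concentrations, gene expression
    (FPKM) and culture metrics (cell number, extracellular glucose and lactate)
    from cell-culture experiments. Provides rule-based temporal pattern
    classification, all-pairs Pearson correlation of profiles across
    heterogeneous time grids, hierarchical clustering of correlation profiles
    with integrated heatmaps, projection of cluster labels onto metabolic
    pathway maps (metabolites as nodes, genes as reaction edges), and
    comparative between-condition correlation mapping with a five-bin display
    scheme. Includes a synthetic time-course generator with planted pattern
    classes, correlation blocks and dose-like perturbations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    igraph,
    mclust,
    pheatmap,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
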