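Package: SymbioMap
Title: Symbiont-Host Effector Interactome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for bipartite effector-host protein interaction
    networks from microbe-plant interactome screens. Implements
    resampling-based null models for intraspecies and interspecies target
    convergence with empirical p-values, shared/exclusive target
    classification, hormone-annotation propagation over a reference host
    interactome (first- and second-degree hormone interaction points and
    functionally informed network assembly with type I/II/III edge
    classification), term-enrichment statistics with reference-coverage
    filtering, dual-reporter protoplast screen normalisation and scoring,
    whole-plant phenotyping metrics (hormone tolerance index, anthocyanin
    content, germination rate, relative expression), rule-based effector
    candidate filtering, and seeded synthetic-data generators with planted
    ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: NetworkInference, GraphAndNetwork, SystemsBiology
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'interactome-io.R'
    'convergence.R'
    'effector-filter.R'
    'enrichment.R'
    'interactome-summary.R'
    'phenotyping.R'
    'screen.R'
    'ships.R'
    'synthetic-data.R'
    'utils.R'
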