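Package: secretomir
Title: Secreted miRNA Biomarker Discovery for Chemical-Induced Neurodegeneration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering secreted microRNA biomarkers of
    chemical-induced neurodegeneration from qPCR array screens. Covers apical
    endpoint dose-response analysis with Dunnett many-to-one comparisons and
    low/high test-concentration selection; detection-limit-censored Ct
    normalization and paired differential expression with Storey q-values and
    Benjamini-Hochberg adjustment; fold-change clustering with average-linkage
    hierarchical clustering and a dynamic tree cut; dual bias-corrected
    hypergeometric pathway enrichment combined by Fisher's method; and
    neurologically-filtered mRNA target prioritization with signed signaling
    cascade tracing. Ships seeded synthetic-data generators emulating the
    statistical structure of TaqMan-style miRNA array experiments so every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
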