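Package: spotnet
Title: Spatial Coexpression and Cis-Element Screening of Transcription
    Factor Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for nominating transcription-factor regulators of
    metabolite pathways from spatial transcriptomics: spot-level quality
    control, normalization and PCA, shared-nearest-neighbour Louvain
    clustering, marker detection, K-means coexpression modules on
    per-cluster pseudo-bulk profiles, position-weight-matrix promoter
    scanning, and a dual-criterion (spatial consistency AND promoter
    binding site) TF-target network with coregulator ranking across
    pathway gene sets. Includes a negative-binomial synthetic tissue
    generator with planted domains, modules, binding sites and a paired
    knockdown experiment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    Biostrings,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
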