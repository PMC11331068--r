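Package: msndev
Title: Adolescent Development of Morphometric Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construction and longitudinal modeling of morphometric similarity
    networks (MSNs) from multimodal regional MRI features. Builds per-scan MSNs
    by robust (median/MAD) standardization and inter-regional Pearson
    correlation, models age trajectories of network hubness with linear
    mixed-effects models in an accelerated longitudinal design, estimates
    structure-function coupling against functional connectomes, computes nodal
    graph metrics (participation coefficient, eigenvector centrality,
    clustering, efficiency) on thresholded functional networks, and provides
    spatial permutation ("spin test") inference for cortical map colocation.
    Includes a synthetic accelerated-longitudinal cohort generator with planted
    cytoarchitectonic-zone effects so that every stage has a parameter-recovery
    test surface, plus ablation, bootstrap and rank-stability robustness
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
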