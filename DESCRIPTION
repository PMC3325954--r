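Package: senecon
Title: Senescence Expression-Signature Concordance and Cell-Based Quantification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studies of premature replicative senescence
    in primary fibroblast cultures. Filters normalized log2 expression matrices
    into directional differential-expression signatures under fold-change and
    p-value cutoffs, quantifies cross-signature overlap and tests directional
    concordance with a 2x2 contingency chi-squared (with a permutation oracle),
    reconstructs DNA-content (ploidy) profiles from per-nucleus stain
    intensities including a greater-than-4N re-replication bracket scheme,
    bins and tests gamma-H2AX focus distributions, summarizes and fits comet
    assay repair kinetics, and provides cumulative-growth, two-reference
    delta-Ct and replicate-proportion utilities. A synthetic-data module
    generates seed-reproducible inputs with planted ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
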