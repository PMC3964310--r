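Package: apmstability
Title: Hybrid Label-Free and Isotope-Labeled AP-MS Interactome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hybrid affinity-purification mass
    spectrometry (AP-MS) interactome studies that combine label-free
    spectral counting with SILAC-based I-DIRT quantification. Provides a
    per-bait Poisson-mixture specificity scorer for spectral counts
    (SAINT-style, with the two-highest-replicate-probability scoring rule
    and per-bait thresholds), ROC-like threshold calibration against a
    reference interaction list, I-DIRT relative-stability ratios from
    light/heavy peptide pairs with input-mixture normalization, a joint
    specificity-by-stability quadrant classification
    (stable/dynamic/rescued/contaminant/nonspecific), hierarchical
    clustering of interaction profiles, NSAF and abundance-normalized
    enrichment indices, network export, and a synthetic AP-MS data
    generator so the whole workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
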