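Package: silacApms
Title: Quantitative Interactor Calling for SILAC/AACT Affinity-Purification
    Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements an end-to-end inference pipeline for dual-tagging
    SILAC/AACT affinity-purification mass-spectrometry (AP-MS) experiments
    that screen for stimulus-induced bait interactors. Covers isotope-pair
    matching of extracted-ion-chromatogram (XIC) features from the leucine-d3
    mass shift, peptide light/heavy ratio computation, PSM filtering with
    charge-dependent Xcorr, deltaCn and probability thresholds plus
    target-decoy FDR estimation, protein ratio aggregation in mean and
    median dialects with log-normal ratio variability statistics, bait
    normalization, derivation of the enrichment cutoff from the average
    relative standard deviation of peptide ratios, bead-proteome exclusion,
    interactor classification, and functional-category / interaction-network
    summarization. Ships a synthetic-experiment generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
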