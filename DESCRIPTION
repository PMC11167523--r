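Package: zfBrainActivity
Title: Whole-Brain Neuronal Activity Quantification for Larval Zebrafish
    Volumetric Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies whole-brain neuronal activity from multi-plane
    two-photon calcium imaging of larval zebrafish expressing nuclear
    GCaMP. Provides ring/disc template-matching segmentation of neuronal
    nuclei, per-cell trace extraction and brain-region assignment,
    trial-averaged evoked (photic) response classification against a
    2-SD baseline criterion, spontaneous-activity metrics built on an
    8th-percentile moving baseline, pairwise correlation-versus-distance
    profiles, and electroretinogram b-wave amplitude quantification.
    A ground-truthed synthetic-data generator emulates the recordings
    (Poisson spiking convolved with a calcium decay kernel, stimulus-locked
    responders and inhibited cells, distance-dependent shared drive,
    rendered nuclear movies and ERG traces) so that every analysis stage
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
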