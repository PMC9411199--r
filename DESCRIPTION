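Package: flyvnc
Title: Analysis of Long-Term Two-Photon Imaging of the Drosophila Ventral
    Nerve Cord
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing chronic two-photon recordings of the
    Drosophila ventral nerve cord and cervical connective together with the
    behavioral modalities acquired alongside them. Provides two-channel
    motion correction (center-of-mass pre-alignment followed by a
    smoothness-regularized variational optic-flow estimator), correction of
    uneven illumination, pixel-wise dF/F computation, spherical-treadmill
    sensor processing and stationary-period classification, synchronization
    of modalities to the imaging frame clock, statistics for
    caffeine-induced activity waves including pixel-wise peak-time maps,
    optogenetically evoked backward-walking metrics from arena trajectories,
    and longitudinal quantification of mechanosensory axon degradation.
    A synthetic-data module generates every input modality with ground truth
    so the full pipeline can be validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
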