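Package: interdigitate
Title: Within-Individual Dissociation of Interdigitated Cortical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dissociating closely
    juxtaposed ("interdigitated") distributed cortical networks within
    single individuals from surface-based functional MRI time series.
    Provides an icosphere surface simulator that plants side-by-side
    network parcels across cortical zones, fMRI-style preprocessing
    (frame discard, zero-phase low-pass filtering, nuisance regression,
    surface smoothing), tSNR and fALFF quality maps, vertex-wise
    Fisher-z connectivity with run averaging and reliability-based
    disattenuation, criterion-driven seed-pair discovery, a balanced
    2x2 ANOVA double-dissociation battery with crossover
    classification, k-means parcellation with recovery scoring, and a
    between-subject misalignment analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    Matrix,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
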