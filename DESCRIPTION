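Package: rnaprobr
Title: Integrative Exploration of RNA Chemical Probing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Parses community-standard file formats for RNA chemical
    probing experiments (SHAPE/DMS MaP reactivities, correlated
    single-molecule probing interactions, base-pairing probabilities,
    secondary and tertiary structure models, structure-drawing layouts,
    and genomic annotations) into five transcript-centric data classes;
    reconciles data measured on different sequences by pairwise
    alignment; automates standard analyses (windowed medians, Shannon
    entropies, low-reactivity/low-entropy region detection, deltaSHAPE,
    windowed AUROC, inter-profile regression, structure-model comparison
    and consensus, 3D contact-distance filtering); and renders
    community-standard visualizations (bar and skyline profiles, arc and
    circle plots, structure diagrams, molecular projections, density
    heatmaps) with machine-readable layout reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    GenomicRanges,
    ggplot2,
    graphics,
    jsonlite,
    MASS,
    rtracklayer,
    stats,
    tools,
    utils,
    grDevices,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
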