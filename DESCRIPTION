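Package: mucoshell
Title: Mucosal Surface Shell Dosimetry for Head and Neck Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises radiotherapy dose to the oral mucosa as an
    anatomically realistic 3 mm surface shell rather than a solid
    oral-cavity volume. Builds mucosal surface contours (MSC) by expanding
    a delineated mucosal sheet into a wall of configurable thickness,
    derives the inward surface annulus of a solid oral-cavity contour
    (OCC), converts physical dose to equivalent dose in 2 Gy fractions
    (EQD2), extracts dose-volume histograms and summary dose metrics, and
    aggregates per-patient OCC-versus-MSC comparisons into cohort medians,
    ranges and median-DVH envelopes. Includes a seeded synthetic
    oral-cavity phantom generator so every stage of the pipeline can be
    exercised and tested without patient data. All morphology is computed
    with Euclidean distance transforms in millimetres, honouring
    anisotropic voxel spacing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
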