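Package: stitchdims
Title: Spectral-Stitching Direct-Infusion Mass Spectrometry Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of low-biomass spectral-stitching
    nanoelectrospray direct-infusion mass spectrometry (nESI-DIMS)
    metabolomics acquisitions in 96-well format: alignment of peaks across
    internal scan replicates within overlapping SIM windows, replicate and
    blank filtering, window stitching, cross-sample alignment into a
    feature matrix, probabilistic quotient normalisation, QC-based signal
    drift correction, repeatability assessment (RSD and median RSD),
    missing-value imputation, generalised-log transformation, PCA,
    FDR-corrected ANOVA with Tukey-Kramer post-hoc tests, and putative
    annotation of features by accurate mass against a compound table.
    Includes a ground-truth-annotated synthetic acquisition simulator
    (plates, SIM windows, scan replicates, blanks, pooled QCs, drift,
    planted class effects) so the full pipeline can be exercised and
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
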