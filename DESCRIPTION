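Package: icspectra
Title: Quantification of the Intercapillary Space Spectrum on En Face OCTA Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and measures intercapillary spaces (the continuum from
    healthy intercapillary areas to capillary nonperfusion areas) on 2D en face
    optical coherence tomography angiography images of the superficial vascular
    plexus. Implements Phansalkar adaptive local thresholding, connected-component
    morphometry (area, chain-code perimeter, minimum and maximum Feret diameters),
    automatic foveal avascular zone identification and exclusion, per-eye spectrum
    summaries (total counts, mean morphometrics, thresholded counts), and the
    cohort statistics used to relate these parameters to diabetic retinopathy
    severity (Kruskal-Wallis with Bonferroni correction, Fisher's exact test,
    Spearman correlation, ROC/AUC with Hanley-McNeil intervals). Includes a
    synthetic en face OCTA generator - a planar capillary mesh with a foveal
    avascular zone, permanent capillary dropout and per-frame transient
    flow-signal loss - with exact ground-truth face polygons for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
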