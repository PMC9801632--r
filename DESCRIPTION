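Package: axodens
Title: Quantification of Dopaminergic Axon and Synaptic Bouton Density in
    Two-Channel Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying fluorescently labeled dopaminergic
    projections in serial brain sections: a synthetic two-channel confocal
    section simulator with exact ground truth (curvilinear axons, point-like
    synaptic boutons, labeled somata, PSF blur, shot and read noise),
    Hessian-ridge axon detection with one-pixel skeletonization,
    Laplacian-of-Gaussian bouton and soma detection with SD-over-background
    thresholding and area gating, cell-count-normalized density measures with
    matched-section bookkeeping and log2 inter-region intensity ratios, and a
    statistical layer (repeated-measures ANOVA with FDR-corrected follow-ups
    and eta-squared, Welch-aware two-sample t tests, Cohen's d, Monte Carlo
    power checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
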