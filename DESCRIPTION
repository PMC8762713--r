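Package: chorovol
Title: Choroidal Vessel Segmentation and Quantification for Volumetric OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the choroidal vasculature in volumetric
    optical coherence tomography (OCT) scans. Provides an image-enhancement
    pipeline (speckle denoising, retinal-vessel shadow reduction, depth
    attenuation compensation, local contrast enhancement), composite 3-D
    choroidal vessel segmentation between Bruch's membrane and the
    choroidal-scleral interface (Niblack local thresholding in B-scan and
    C-scan views combined with global Otsu thresholding), quantitative
    en-face vessel-volume and choroid-volume maps with ETDRS-grid regional
    aggregation and the choroidal vessel index, synthetic layered phantoms
    with known vessel ground truth, and ROC-based diagnostic statistics for
    cohort summaries of the resulting metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    tibble,
    generics,
    rlang,
    withr,
    ggplot2,
    EBImage,
    stats,
    utils,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
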