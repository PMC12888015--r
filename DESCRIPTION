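Package: morphomsi
Title: Morphology-Guided Annotation and Spectral Comparison for MALDI Mass
    Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open pipeline for morphology-guided annotation of MALDI mass
    spectrometry imaging (MSI) data of tissue microarrays. A small pixel
    classifier trained on multiscale colour and texture features of H&E
    images selects cell-rich regions; pathologist diagnosis labels are
    transferred to the detections, which are tiled onto the coarser MSI spot
    grid. Downstream tools read and write imzML, normalise spectra, pick
    peaks by signal-to-noise, and compare region-of-interest types by
    interferent-panel scoring, PCA and per-feature ROC/AUC. A synthetic
    fixture generator produces paired H&E-like images and imzML cubes with
    known ground truth so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    xml2,
    yaml,
    grDevices,
    png
Suggests:
    cluster,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
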