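Package: satquant
Title: Semi-Automated Counting of Pax-7 and BrdU Positive Nuclei in Muscle Immunofluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Image-processing pipelines for quantifying satellite-cell markers in
    multi-channel immunofluorescence micrographs of skeletal muscle. Provides the
    channel-specific processing chains for DAPI, Pax-7 and BrdU images (rolling-ball
    background subtraction, sharpening, Sobel edge enhancement, min-max luminance
    normalization, kernel convolution, median filtering, watershed splitting of
    touching nuclei), three histogram auto-thresholding algorithms (mean, Renyi
    entropy, Intermodes), binary morphology and connected-component counting,
    pairwise marker co-positivity quantification with nucleus gating, a seeded
    synthetic-section generator with exact ground truth, batch processing over
    section manifests, and ordinary-least-squares validation of automated against
    manual counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
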