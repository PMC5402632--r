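Package: cortibreak
Title: Automated Detection of Small Cortical Interruptions in HR-pQCT
    Images of Finger Joints
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automated detection and quantification of small cortical
    interruptions (cortical bone breaks of at least 3 voxels in-plane width
    spanning at least 3 consecutive slices) in 3D high-resolution peripheral
    quantitative computed tomography (HR-pQCT) volumes of finger joints.
    Provides periosteal auto-contouring by Gaussian thresholding and 3D
    morphological closing, Laplace-Hamming bone segmentation, construction of
    a constant-thickness cortical mask, through-pore connectivity detection
    with interruption volume and surface quantification, a synthetic phantom
    generator with exact ground truth, and reliability statistics (overlap
    matching of interruption label maps, proportion of matching interruptions,
    positive predictive value, sensitivity, and two-way random absolute
    agreement intraclass correlation ICC(2,1)).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    tiff,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
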