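Package: veinforge
Title: Ensemble Speckle-Adapted BM3D Denoising and Unsupervised Retinal
    Vessel Segmentation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Unsupervised segmentation of blood vessels in retinal fundus
    photographs built around an ensemble of speckle-adapted block-matching 3D
    (S-BM3D) filters. The denoiser groups self-similar patches with a
    likelihood-based distance for multiplicative square-root-Gamma speckle,
    shrinks them collaboratively in a redundant wavelet domain (LLMMSE first
    pass, empirical Wiener second pass), and aggregates overlapping estimates;
    averaging an ensemble of such filters over a grid of block sizes and
    search windows suppresses the checkerboard artifacts a single filter
    leaves behind. The segmentation pipeline chains contrast-limited adaptive
    histogram equalization, the ensemble denoiser, a Hessian eigenvalue-ratio
    vesselness filter or a multiscale oriented second-derivative line
    detector, Perona-Malik anisotropic diffusion and ISODATA thresholding,
    and ships a synthetic fundus phantom generator with known vessel ground
    truth plus field-of-view restricted evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    Rcpp,
    EBImage,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
biocViews: Software, Visualization, Segmentation, Preprocessing
RoxygenNote: 7.3.3
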