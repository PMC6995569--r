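Package: cryopick
Title: Unsupervised Particle Picking and Segmentation for Cryo-EM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised single-particle picking and segmentation for
    low signal-to-noise cryo-electron micrographs. Builds a multi-scale
    representation by successive Perona-Malik anisotropic diffusion and
    difference-of-Gaussians stacking, separates structure from background
    with a rank-2 non-negative matrix factorization, extracts size-gated
    region candidates with Otsu thresholding and connected components,
    filters false positives by cepstrum analysis of polar-unwrapped
    patches, and segments each accepted particle with geodesic border
    closing, a Fourier boundary descriptor and direct least-squares
    ellipse fitting. Includes a synthetic micrograph simulator with
    pink-noise background and annular/rectangular particles at known
    coordinates, and an evaluation module computing recall, precision,
    F1 and centroid-offset statistics against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
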