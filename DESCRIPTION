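Package: vffr
Title: Virtual Fractional Flow Reserve and Wall Shear Indices from Coronary Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for estimating fractional flow reserve (FFR)
    and wall shear stress indices in stenosed coronary arteries from
    two-dimensional angiographic cine frames. Provides synthetic angiogram and
    pressure-wave generators with known ground truth, lumen segmentation and
    centerline extraction, stenosis quantification, surface-of-revolution lumen
    reconstruction with boundary-layer-graded axisymmetric grids, a transient
    finite-volume incompressible Navier-Stokes solver with Carreau-Yasuda
    shear-thinning rheology and three-element Windkessel outlet coupling under
    four boundary-condition methodologies, and post-processing of FFR, TAWSS,
    OSI and RRT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png,
    minpack.lm,
    igraph,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
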