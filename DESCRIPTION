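Package: vesselcaliper
Title: Retinal Blood-Vessel Diameter Measurement from Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computerized measurement of retinal blood-vessel calibers from
    fundus photographs or hand-labeled vessel maps. The pipeline binarizes
    the image by thresholding, thins the vessel network to a one-pixel
    skeleton (Zhang-Suen), classifies skeleton pixels into endpoints, inner
    and bifurcation points with a 3x3 neighborhood mask, reduces each
    centerline branch to characteristic points with the Douglas-Peucker
    algorithm, detects vessel edges with a greedy active contour (snake)
    minimizing continuity, curvature and Gaussian-gradient energies, and
    estimates the local diameter as the sum of two triangle heights obtained
    from Heron's formula on characteristic-point/contour-point triangles.
    Includes a synthetic vessel-phantom generator with known ground truth
    and the paired manual-versus-method evaluation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    methods,
    pixmap,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
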