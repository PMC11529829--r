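Package: petcc
Title: Dual-Mode PET and Compton-Camera Imaging with a Dual-Panel CZT Scanner
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and reconstruction pipeline for a dual-panel
    edge-on cadmium zinc telluride (CZT) scanner operated simultaneously as a
    PET camera and as a Compton camera. Provides a synthetic photon-transport
    simulator for non-pure positron emitters (positron range, prompt gammas,
    Compton and photoelectric interactions in CZT), truth-labelled coincidence
    sorting into list-mode text formats, list-mode MLEM reconstruction with an
    orthogonal-distance ray-tracer projector for lines of response and a
    cone-surface projector with energy-based Gaussian angular kernels for cones
    of response, and profile/FWHM analysis with Gaussian and Lorentzian fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
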