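Package: lashear
Title: Left Atrial Wall Shear Stress, Blood Age and Fibrosis Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between regional left atrial
    hemodynamics and atrial fibrosis. Generates idealized labeled left-atrial
    surface meshes with pulmonary vein tubes, an appendage pouch and a mitral
    orifice; standardizes geometry (flow extensions, pulmonary vein clipping);
    provides a desk-scale potential-flow surrogate driven by a mitral inflow
    waveform and a blood-age advection-diffusion solver with unit source;
    computes the canonical wall shear indices (TAWSS, OSI, ECAP, RRT, HOLMES,
    WSSG) from per-vertex traction series; aligns electroanatomical point
    clouds by rigid iterative closest point and transfers bipolar voltage and
    image intensity ratio fields by radial basis function interpolation;
    unfolds the atrial wall to a 2D template with the mitral rim pinned to the
    perimeter and partitions it into 24 standardized regions; and reproduces
    the quartile, correlation and contingency statistics used to relate wall
    shear to fibrosis and electrical scar.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    tibble,
    rlang,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
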