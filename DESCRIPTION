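Package: polstokes
Title: Polarized Light Monte Carlo Transport in Voxelated Turbid Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based Monte Carlo simulation of polarized light
    transport in heterogeneous turbid media. Per-medium scattering
    matrices and bulk optical properties (scattering coefficient,
    anisotropy) are precomputed from Mie theory for populations of
    spherical scatterers; photon packets carry a Stokes vector tracked
    in the meridian-plane formalism through rejection-sampled polarized
    scattering events; backscattered I, Q, U, V are accumulated on a
    pixelated area detector. Includes layered-slab and
    spherical-inclusion benchmark scenes and a log10-scale RMSE image
    comparison metric.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
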