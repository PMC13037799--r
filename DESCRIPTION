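Package: phantomdose
Title: Polygon-Mesh Human Phantom Engineering and Photon Dosimetry
Version: 0.1.0
Authors@R:
    person("phantomdose", "developers", email = "phantomdose@example.org",
           role = c("aut", "cre"))
Description: Tools for building, checking and irradiating computational human
    phantoms described as region-tagged polygon surfaces, tetrahedral meshes
    or voxel rasters.  Includes readers and writers for Wavefront OBJ,
    TetGen ELE/NODE and ASCII voxel formats; watertightness and
    self-intersection quality control; mass-targeted scaling and
    radiosensitive shell-layer construction (skin basal layer, anterior
    lens); homogenized skeletal material accounting over 20 anatomical bone
    regions; a compiled analog Monte Carlo photon transport kernel under the
    kerma approximation with Woodcock delta-tracking and Klein-Nishina
    incoherent scattering; fluence-spectrum marrow and endosteum dose
    estimators; and ICRP Publication 103 sex-averaged effective dose
    aggregation.  Deterministic stylized phantom generators make the whole
    pipeline exercisable without external anatomical datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
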