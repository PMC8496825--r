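Package: hdring
Title: Head-Direction Ring Attractor with Learned Landmark Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate simulation of the head-direction (HD) system in
    visually complex environments. A ring attractor integrates angular
    velocity; feature-specific visual channels drive a competitive layer of
    abstract landmark-bearing (aLB) cells trained with a non-negative,
    laterally inhibited variant of Oja's Subspace Algorithm; retrosplenial
    layers associate the landmark signal with the HD signal through Hebbian
    plasticity with norm capping and return corrective feedback to the
    attractor. Includes declarative scenery and protocol builders for
    multi-cue, multi-environment experiments, synthetic head-direction
    trajectories, population-vector decoding, tuning-curve and remapping
    (Jaccard) diagnostics, and alternative plasticity rules for comparison
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
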