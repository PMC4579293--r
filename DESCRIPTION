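Package: tractdissect
Title: Virtual Dissection of White-Matter Pathways by Probabilistic
    Tractography on Synthetic Diffusion Phantoms
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates diffusion-weighted MRI phantoms with known fiber
    bundle geometry, fits a ball-and-stick orientation model per voxel by
    nonlinear least squares followed by Metropolis posterior sampling,
    propagates probabilistic streamlines under seed, waypoint, termination
    and exclusion region-of-interest semantics, and implements a virtual
    dissection protocol for an arcing superior colliculus to amygdala
    pathway with a crossing stria-terminalis decoy bundle: visitation-map
    thresholding, exclusion-mask re-tracking, bidirectional overlap,
    cross-subject composites, per-slice centre-of-gravity variability
    statistics, and lesion-interruption reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
VignetteBuilder: knitr
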