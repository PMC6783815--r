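Package: morphoct
Title: 3D Morphometrics of Irregular Plant Bodies from Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("morphoct", "developers", email = "morphoct@example.org",
           role = c("aut", "cre"))
Description: Quantifies irregular three-dimensional plant morphology from
    X-ray micro-computed tomography volumes. Provides a mask-based
    pipeline that isolates the binary plant body from a scene containing
    a high-intensity pedestal and tube-case artifacts, iso-surface
    meshing and 3D convex-hull shape descriptors (convexity = hull
    surface area over object surface area; solidity = object volume over
    hull volume), two-class linear discriminant analysis with Cohen's
    kappa for separating morphological groups, and a synthetic phantom
    generator (flat and twisted/undulating thallus-like sheets with
    analytic ground truth) so the whole pipeline is testable without
    external data. Volumes are read and written as multi-page TIFF
    stacks; descriptor tables as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
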