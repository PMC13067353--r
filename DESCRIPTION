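Package: protonpath
Title: Hydration-Coupled Proton-Transfer Free-Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing hydration-coupled proton transport through
    protein channels with biased sampling in collective-variable space.
    Builds curvilinear proton-transfer pathways from water-oxygen clouds by
    principal-curve fitting, computes water-wire connectivity and
    path-progress collective variables, reconstructs 1D/2D free-energy
    surfaces from umbrella-sampling windows (WHAM with block-averaged
    uncertainties) and from multiple-walker well-tempered metadynamics hill
    logs, extracts minimum free-energy paths with projected profiles and
    barriers, and converts barriers to Eyring transition-state-theory rates.
    A built-in overdamped Langevin sampler on parameterised model surfaces
    generates all inputs synthetically so the full pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
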