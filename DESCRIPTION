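Package: ecmremodel
Title: Discrete Fiber-Network and Continuum Viscoplastic Simulation of
    Cell-Driven Extracellular Matrix Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates force-driven plastic remodeling of fibrous
    extracellular matrices (collagen I, fibrin) at two scales. A discrete
    crosslinked fiber network engine combines harmonic stretch and bend
    fiber mechanics, segment volume exclusion, crosslink springs with
    Bell-model (slip bond) force-sensitive stochastic unbinding and
    optional rebinding, overdamped Euler dynamics, and a dynamic
    filopodial loading zone, yielding fiber concentration profiles,
    accumulation time series and cross-plane stress under load-and-release
    protocols. A spherically symmetric continuum solver couples
    Norton-Hoff power-law viscoplasticity with irreversible exponential
    elastic damage and linear plastic softening, reporting recoverability
    indices, half-max damage radii and the error of naive elastic traction
    back-calculation. Experimental remodeling metrics (displacement
    length, densification factor, recoverability index, radial decay
    profiles) operate on gridded displacement fields and intensity
    volumes, with a synthetic fixture generator for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
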