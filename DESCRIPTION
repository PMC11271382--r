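Package: pmfront
Title: Porous-Medium Invasion Fronts in Heterogeneous Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates biological invasion governed by a KPP-type reaction
    with porous-medium (degenerate) nonlinear diffusion in a spatially
    heterogeneous carrying-capacity landscape.  Provides a phase-plane
    shooting solver for the sharp minimal-speed traveling wave and its
    minimal speed c0(m), a singularly perturbed finite-volume solver for the
    hyperbolic-scale reaction-diffusion problem, the sharp-interface limit
    dynamics V_n = c0 * k(x)^((m-1)/2) as a 1-d front ODE and a 2-d level-set
    flow, and diagnostics that extract fronts, estimate speeds, and check the
    interface generation and propagation predictions numerically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
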