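Package: phototrax
Title: Phototactic Active-Particle Dynamics in Traveling Light Pulses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates overdamped active Brownian particles whose propulsion
    speed follows the local light intensity and whose orientation is steered
    by an aligning torque toward the intensity gradient. Provides
    piecewise-linear traveling light pulses and pulse trains, an
    Euler-Maruyama integrator for the coupled translational and orientational
    Langevin equations, ensemble observables (mean displacement, slope
    residence times, orientation distributions, drift velocities,
    size-sorting metrics), canned simulation protocols, and a command-line
    interface. Reproduces the "diffusing wave paradox": net particle
    transport counter to a traveling stimulus pulse.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
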