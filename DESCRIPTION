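Package: hurpdyn
Title: Spatiotemporal Modelling of HURP Dynamics on Kinetochore-Fibres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minimal advection-diffusion-reaction model of the
    microtubule-associated protein HURP along kinetochore-fibres, with a
    GTP-cap/mixed-nucleotide binding profile, a RanGTP activity gradient and
    partially adsorbing (Robin) boundaries. Provides the deterministic
    forward solver, Bayesian parameter inference by random-walk Metropolis
    on log-transformed parameters with pilot-tuned proposals, synthetic
    line-profile/particle-trace/FRAP generators, and downstream analyses:
    HURP-gap sensitivity sweeps, simulated and double-normalised FRAP
    recovery fitting, and mean-squared-displacement diffusion estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
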