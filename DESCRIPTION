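Package: flowerscape
Title: Stochastic Landscape Analysis of the miR156/miR172 Flowering-Time Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the miR156/miR172-regulated flowering-time gene network of
    Arabidopsis thaliana as a six-variable Hill-function dynamical system driven
    by atmospheric CO2, with additive Gaussian noise. Provides deterministic
    fixed-point and bifurcation analysis, Euler-Maruyama simulation of the
    Langevin dynamics, estimation of the non-equilibrium potential landscape
    U = -ln(Pss) projected onto the AP2/AP1 plane with basin and saddle
    detection, first-passage-time (flowering-time) statistics, and the derived
    computational experiments: CO2 scans, regulation-strength scans, feedback
    knockouts, and global sensitivity analysis of the mean first passage time.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
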