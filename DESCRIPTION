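Package: motifsim
Title: Numerical Analysis of Microbial Ecological Interaction Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemostat-style ordinary differential equation models of common
    two- and three-species microbial interaction motifs (syntrophy,
    commensalism, predation, amensalism, competition, and a three-tiered
    food web), with a catalogue of growth-kinetic forms. Provides stiff
    time integration, systematic enumeration of nonnegative fixed points by
    damped-Newton multistart over biomass washout subsets, eigenvalue and
    Routh-Hurwitz stability classification, two-parameter operating
    diagrams (steady-state existence and stability regions), basin-of-
    attraction mapping over initial conditions, and coupling of growth
    kinetics to reaction thermodynamics through a Gibbs-energy inhibition
    factor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
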