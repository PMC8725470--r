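Package: crnbistab
Title: Detecting Switch-Like Bistability in Mass-Action Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural and numerical analysis of mass-action chemical
    reaction networks with moiety conservation laws. Builds the network's
    stoichiometric and kinetic matrices from an SBML file or a plain-text
    reaction list, classifies linkage and terminal strong linkage classes,
    computes a nonnegative integer basis of conservation laws by a
    vertex-search linear program, reduces the system to an independent set
    of ODEs, and searches for saddle-node bifurcations by constrained
    multistart global minimization of the squared Jacobian determinant with
    a Bayesian stopping rule. Candidate saddle-nodes are confirmed by
    pseudo-arclength continuation of the equilibrium branch or by direct
    stiff simulation of the dose-response curve with hysteresis detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
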