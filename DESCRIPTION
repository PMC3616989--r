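Package: fadyn
Title: Kinetic Modelling of Focal Adhesion Assembly and RNA Interference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for a twelve-species kinetic model of integrin-based
    cell-matrix adhesions. Couples hierarchical assembly of focal complexes
    from actin, connector and integrin components with force-dependent
    maturation into focal adhesions under slip-bond or catch-bond
    dissociation, Rac/Rho double-negative feedback signalling, and
    Hill-kinetic siRNA-mediated mRNA knockdown. Provides steady-state
    analysis with a long-horizon verification protocol, one-parameter
    bifurcation sweeps of the bistable Rac/Rho regime, knockdown scenario
    runners (mRNA targets, Rho depletion, an auxiliary degradation
    regulator), and metabolic control analysis via concentration control
    coefficients with summation-theorem validation over geometrically
    interpolated parameter ensembles.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
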