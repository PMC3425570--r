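Package: hsp90net
Title: Modular Kinetic Modelling and Bifurcation Analysis of the HSP90
    Heat-Shock Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles the three-module mass-action kinetic model of the
    HSP90 heat-shock network (HSF1 trimerization, phosphorylation-
    dephosphorylation of the trimer:HSE complex, and the ATP-assisted
    open-to-closed conformational cycle of HSP90), integrates the resulting
    stiff 27-state ODE system, fits its kinetic constants to percent-of-max
    time courses with a scatter-search global optimizer, computes local
    relative sensitivity indices and the parameter identifiability
    correlation matrix, and performs one-parameter pseudo-arclength
    continuation in the stress strength with limit-point and Hopf detection
    and rule-based classification of the resulting diagrams into hysteresis,
    mushroom and isola topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
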