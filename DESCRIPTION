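Package: enzfeed
Title: Model-Based Enzymatic Glucose Release for Small-Scale Fed-Batch Cultivation
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for planning and simulating enzyme-mediated glucose feeding in
    miniaturized fed-batch cultivations. Implements a two-fraction Michaelis-Menten
    model of glucoamylase-catalysed dextrin hydrolysis with event-driven bolus
    simulation (additions, sampling, dilution, evaporation), simultaneous
    multi-experiment kinetic parameter estimation with model-variant comparison
    (self-adaptive differential evolution plus bounded Levenberg-Marquardt polish),
    a feed planner that computes grid-timed enzyme and dextrin additions realizing
    exponential glucose-release setpoints, a macro-kinetic Escherichia coli growth
    coupling for end-to-end cultivation simulation, and a synthetic-data generator
    emulating the cell-free release and fed-batch experiment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
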