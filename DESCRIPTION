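Package: adcsim
Title: Multiscale Simulation of Antibody-Drug Conjugate Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A quantitative systems pharmacology simulator for antibody-drug
    conjugates (ADCs). Implements an in vitro cellular disposition model
    (receptor binding, internalization, recycling, degradation, and linker
    cleavage-dependent payload release), mouse and human plasma
    pharmacokinetics with soluble-target and healthy-tissue receptor sinks,
    Krogh-cylinder tumor uptake with size-dependent exchange, a
    transit-compartment tumor growth inhibition model driven by intracellular
    payload concentration, weighted least-squares calibration, Latin
    hypercube / partial rank correlation global sensitivity analysis, and
    virtual clinical trial simulation with RECIST classification and
    progression-free survival curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    Matrix,
    ggplot2
Config/testthat/edition: 3
NeedsCompilation: yes
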