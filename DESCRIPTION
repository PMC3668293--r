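Package: insox
Title: Kinetic Modelling of Insulin Signalling Under Oxidative Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic kinetic model of the insulin signalling pathway in
    rodent adipocytes coupled to reactive oxygen species (ROS) signalling and
    FOXO-mediated transcriptional feedback. Builds the reaction network in
    particle-number units from printed parameter tables (receptor binding,
    IRS1 regulation, Akt/AS160/GLUT4, phosphatase redox and ROS transport,
    JNK/IKK activation), enumerates the combinatorial FOXO
    post-translational-modification state space by rule, wires FOXO-driven
    transcription of the insulin receptor and SOD2 back into the network, and
    integrates the resulting stiff ODE system with event schedules for
    insulin and external oxidant dosing. Includes scripted scenarios for
    insulin step responses, dose-response curves, fasting, insulin-oxidant
    interaction and oxidative-stress preconditioning, plus SBML Level 3
    export of assembled models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
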