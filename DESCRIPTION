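Package: grncompare
Title: Comparative Modeling and Reverse Engineering of Gene Regulatory
    Networks with ANN, S-System and GRLOT Rate Laws
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a comparative study of three continuous deterministic
    formalisms used to model gene regulatory networks: recurrent
    artificial-neural-network (ANN) rate laws, S-system power-law kinetics,
    and the general rate law of transcription (GRLOT).  The package builds
    parameterized five-gene reference networks, simulates noise-free
    time-series expression data from them, reverse-engineers models with a
    two-phase (node-then-network) real-coded evolutionary algorithm, and
    scores the results with predictive (P_ver, P_val), inferential (P_inf)
    and qualitative (Q_com) measures, including a perturbation-based
    validation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
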