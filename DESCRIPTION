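Package: pbsquench
Title: Forster Energy Transfer and Stochastic Exciton Quenching in
    Phycobilisome-Carotenoid Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models excitation energy transfer and carotenoid-mediated
    quenching in cyanobacterial phycobilisomes. Extracts chromophore
    geometry from PDB/mmCIF structures, computes excitonic couplings by
    the transition-charge (TrEsp) and point-dipole methods, builds
    Forster rate matrices from spectral overlap integrals with detailed
    balance, and simulates single-exciton decay by the Gillespie
    algorithm, with a master-equation solver as deterministic reference.
    Includes a synthetic phycobilisome generator so the full pipeline
    runs without external structure files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
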