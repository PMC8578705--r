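Package: quantalCa
Title: Quantal Calcium Release from ER Stores by IP3 Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of quantal Ca2+ release from the
    endoplasmic reticulum through inositol 1,4,5-trisphosphate receptors
    (IP3Rs). Provides tetrameric ligand-occupancy arithmetic and receptor
    pharmacology (Hill fits, Cheng-Prusoff and Schild corrections, binding
    energetics), a stochastic three-state (closed/open/inactivated) gating
    simulator for tetra-liganded receptors with a deterministic
    master-equation counterpart, a deterministic ER luminal Ca2+ store model
    with leak, IP3R release and SERCA refill, the inverse analysis that
    reconstructs open-receptor time courses from luminal Ca2+ fluorescence
    traces after leak correction, and a synthetic plate-reader data
    generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    minpack.lm,
    pracma,
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
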