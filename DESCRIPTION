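Package: polfx
Title: Correlative Optical-Tweezers and Fluorescence Analysis of DNA Polymerase Exchange
Version: 0.1.0
Authors@R: person("polfx", "maintainers", email = "polfx@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for correlative dual-trap optical tweezers and
    confocal fluorescence experiments on DNA polymerase exchange at the
    ssDNA/dsDNA replication junction. Reconstructs the junction trajectory
    from force and end-to-end distance using freely-jointed-chain (ssDNA) and
    extensible worm-like-chain (dsDNA) elasticity, registers and quantifies
    fluorescence kymographs, detects activity bursts and pauses by
    change-point step fitting, computes memory-effect and activity-by-
    fluorescence correlation statistics, and estimates binding lifetimes
    (with photobleaching correction) and diffusion constants. Includes a
    ground-truthed stochastic simulator of polymerase-exchange kinetics,
    force-extension traces and photon-count kymographs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
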