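Package: coagsim
Title: Mass-Action Simulation of the Blood Coagulation Cascade with
    Virtual Clotting Assays, Anticoagulant Mechanisms and Flow Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A unified mass-action reaction-network model of the blood
    coagulation cascade covering the extrinsic (tissue-factor) and
    intrinsic (contact) pathways, fibrinogen cleavage, the protein C/S
    negative feedback, phospholipid adsorption and antithrombin
    inhibition.  The package provides a stiff ODE simulation engine with
    threshold-crossing detection, virtual prothrombin time (PT),
    activated partial thromboplastin time (aPTT), INR and thrombin
    generation assays, mechanistic models of the anticoagulants
    rivaroxaban, DX-9065a, melagatran and enoxaparin plus a warfarin
    initial-condition representation, an open-system extension coupling
    the clotting region to a flowing blood pool with a critical washout
    threshold (alpha_crit), and a benchmarking layer that classifies
    dosing regimens as safe and/or efficacious against warfarin
    reference therapies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
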