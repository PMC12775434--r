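Package: screenfunnel
Title: Post-Docking Triage, Calibration and Pharmacology Analysis for
    Ultra-Large Virtual Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for the computational funnel used in
    structure-based ligand discovery campaigns against G protein-coupled
    receptors: lead-like and interference (PAINS) filtering, novelty
    filtering against known actives, score-ordered leader clustering on
    Morgan fingerprints, ranked shortlist construction, property-matched
    decoy generation with enrichment metrics (EF1%, adjusted logAUC),
    quantitative pose evaluation (Kabsch superposition, symmetry-aware
    ligand RMSD, contact recovery, residue displacement, polar contacts),
    SMARTS-based analog expansion, and pharmacological screen analysis
    (two-addition agonist/antagonist classification, four-parameter
    logistic concentration-response fitting, potency ratios, and
    brain-to-plasma exposure ratios). Synthetic-data generators emulate a
    screening campaign end to end so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    minpack.lm,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
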