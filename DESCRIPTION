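Package: xldyn
Title: Cross-Link Guided Assembly Modeling and Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating and refining models of multi-subunit
    protein assemblies against chemical cross-linking mass spectrometry
    (CL-MS) data, and for analysing their dynamics. Implements per-linker
    Ca-Ca distance budgets (spacer plus side-chain and backbone-dynamics
    allowances), mapping of Lys-Lys cross-links onto homo-oligomeric
    assemblies with minimum-over-copies ambiguity resolution,
    restraint- and clash-based filtering of rigid-body docking poses with
    Ward clustering and medoid representatives, and trajectory/ensemble
    analyses: Kabsch superposition RMSD, per-residue RMSF, fraction of
    native contacts (Q), inter-chain contact maps, hydrogen-bond
    occupancy, anisotropic network model (ANM) normal modes with mode
    animation, and principal component analysis. Seeded synthetic
    generators of toy assemblies, planted docking poses with consistent
    cross-link sets, and noise trajectories provide a fully reproducible
    test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
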