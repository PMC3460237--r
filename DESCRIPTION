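Package: pocketfunnel
Title: Hierarchical Structure-Based Virtual Screening Funnel for
    Cation-Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable toolkit for hierarchical in silico screening
    against nicotinic-receptor-like ligand binding domains. Provides
    receptor structure preparation and binding-pocket extraction,
    closed-form Calpha superposition with per-residue RMSD profiles,
    ligand standardization with cationic-center triage and stereoisomer
    enumeration, protein-derived excluded-volume pharmacophore screening
    with a certified rigid-placement search, post-docking geometric
    filters (cation-pi distance, pocket containment, steric clashes,
    hydrogen-bond annotation), score ranking with shortlist export,
    circular-fingerprint novelty screening against known-ligand reference
    sets, and a deterministic funnel orchestrator with stage manifests.
    Synthetic fixture generators with planted, machine-checkable outcomes
    make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    yaml
SystemRequirements: OpenBabel (obabel on the PATH) for SMILES import and
    3D conformer embedding
Config/testthat/edition: 3
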