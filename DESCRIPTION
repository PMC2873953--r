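Package: dockfp
Title: Interaction-Fingerprint Analysis of Protein-Protein Docking Decoys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-docking analysis of protein-protein docking decoy ensembles
    using residue-pair interaction fingerprints. Reads multi-model PDB files,
    detects non-bonded heavy-atom contacts across a receptor-ligand interface,
    encodes them as residue-pair bit fingerprints, and compares decoys with
    Tversky-family similarities (Tanimoto index, native-recovery fraction
    S_frac) or with receptor-anchored ligand RMSD after Kabsch superposition.
    Decoys are clustered with UPGMA dendrograms cut by threshold or into k
    groups, and near-native decoy groups are discriminated by energy-score
    uniformity, blind low-energy selection, and per-residue interaction
    frequency maps. A self-contained synthetic decoy generator emulates
    receptor conformer ensembles with a planted near-native subpopulation so
    the whole pipeline is testable without external structure downloads.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
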