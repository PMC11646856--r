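Package: tcrflex
Title: Conformational-Change Analysis of TCR:pMHC-I Binding Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies conformational changes between unbound (apo) and
    bound (holo) states of alpha/beta T cell receptors (TCRs) and class I
    peptide-MHC complexes from IMGT-numbered PDB structures. Provides
    framework- and groove-floor-based rigid superposition, backbone and
    per-residue heavy-atom RMSD, dihedral D-scores, anchor-aligned dynamic
    time warping distances between CDR loop conformations with
    density-based (HDBSCAN-style) canonical clustering, TCR-to-pMHC
    heavy-atom contact fingerprinting, peptide anchor-motif analysis,
    entity-normalised nonparametric statistics, and a seeded generator of
    synthetic structures with known ground-truth motions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
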