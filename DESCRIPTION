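Package: gbamap
Title: Residue-Level NMR Perturbation Mapping of GBA-Motif Binding to G-Alpha Subunits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for localizing the binding of GBA-motif
    (G-alpha-binding-and-activating) peptides on G-alpha subunits from 2D
    NMR peak lists. Transfers published backbone-amide assignments onto
    experimental TROSY/HSQC peak lists with robust estimation of systematic
    referencing offsets, tracks assigned peaks through a ligand titration,
    computes per-residue chemical shift perturbations and free/bound
    intensity ratios with reference-signal normalization, a 1% detection
    floor and median-multiple significance classes, projects composite
    perturbation classes onto a PDB structure and summarizes them over
    annotated regions (G-boxes, switches, secondary structure), and fits
    the downstream mutant panel: one-site fluorescence-polarization binding
    hyperbolas, mutant-versus-wild-type Kd fold-change matrices with
    cross-ligand correlation, and GEF-activity normalization with
    inhibition classes. A seeded synthetic-data module generates peak
    lists, titrations, binding curves and activity tables with ground
    truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
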