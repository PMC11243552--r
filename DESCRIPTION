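Package: ligandscape
Title: Structure-Affinity Landscapes and Binding-Mode Comparison for
    Ligand Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for quantitative ligand-screening workflows built
    around docking output: structure-activity and structure-binding-affinity
    landscape indices (SALI/SBAI) with activity-cliff detection and
    network-like similarity graphs; binding-mode fingerprints with
    Manhattan, Euclidean and signed-additive distances and the
    root-mean-square binding-mode deviation (RMSD_BM); geometric detection
    of hydrogen bonds, halogen bonds and hydrophobic contacts in
    protein-ligand complexes; and per-residue flexibility difference maps
    from crystallographic B-factors or simulation RMSF profiles. Includes
    a designed library of halogenated benzimidazole nucleoside ligands,
    packaged docking energy tables for the CK2alpha, PIM-1 and RIO1 kinase
    targets, and synthetic fixture generators with planted interaction
    geometries and planted activity cliffs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
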