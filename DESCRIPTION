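Package: sascliffs
Title: Structure-Activity Landscapes, Activity Cliffs and Mechanism-of-Action
    Cliffs for Chemical Bioactivity Datasets
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Curates tabular chemical bioactivity datasets (SMILES with log-AC50
    activities and hit calls), builds structure-activity similarity (SAS) maps
    from ECFP4/Tanimoto fingerprint comparisons, detects activity cliffs and
    activity cliff generators, derives matched molecular pairs (MMPs) by
    fragment-and-index enumeration with size-restriction criteria and calls
    MMP-cliffs, classifies cliffs into seven structural types from
    Bemis-Murcko scaffolds, cyclic skeletons and R-group decompositions, and
    classifies dual-endpoint (agonist/antagonist) chemical pairs into strong,
    same and weak mechanism-of-action categories. Includes a seeded synthetic
    data generator with planted ground truth for end-to-end validation, and a
    command-line pipeline. Molecular primitives are computed through a bundled
    Python RDKit helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the RDKit package available on PATH
    as 'python'
Imports:
    data.table,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
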