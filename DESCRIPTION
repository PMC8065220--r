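Package: DisulfideArch
Title: Disulfide Bond Architecture of ER Cargo Under Hypoxia
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for profiling the disulfide bond architecture of
    endoplasmic reticulum (ER) cargo proteins and relating it to hypoxia
    inducibility. Parses a UniProt-style tab-separated annotation dialect
    into protein records, filters records to secreted and membrane ER
    cargo, splits cargo by transcriptional induction under anoxia,
    computes per-protein disulfide metrics (bonds per 100 amino acids,
    bond ranges, fraction of cysteines bonded, free cysteines) with
    cytosolic portions of membrane proteins excluded, and compares groups
    with exact or normal-approximation Mann-Whitney tests. Also quantifies
    pulse-chase densitometry fractions (secretion, dimerisation, Golgi
    maturation, oxidative folding fitness) and membrane localization from
    calibrated fluorescence images via micron-scaled morphological
    dilation. Synthetic-data generators emulate every input class with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Proteomics, StructuralPrediction, StatisticalMethod, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
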