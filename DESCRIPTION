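Package: nucmet
Title: Metal-Nucleotide Coordination Modes and ATP Dissociation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies divalent-cation coordination modes of ATP and AMP-PNP
    in macromolecular structures using a soft-minimum ion-coordination number
    per phosphate group, and runs a survey pipeline (resolution, redundancy
    and concurrent-cation filters) producing mode occurrence tables. Analyzes
    ligand-unbinding trajectories of trimeric receptors: binding-site distance
    series, dissociation-event counting, logistic dissociation-probability
    fits versus an interaction-scaling factor, snapshot selection and
    subunit-averaged 3D occupancy density maps. Includes an equilibrium
    speciation solver for metal-ATP recording solutions and synthetic-data
    generators for structures and trajectory ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
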