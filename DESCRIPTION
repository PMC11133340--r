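Package: eetnet
Title: Excitation Energy Transfer Networks from Pigment-Protein Structures
Version: 0.1.0
Authors@R: person("Maintainer", "eetnet", email = "eetnet@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the pigment organisation of photosynthetic
    pigment-protein supercomplexes from atomic models. Reads mmCIF and PDB
    coordinate files, extracts chlorophyll, carotenoid and lipid cofactors
    into a typed inventory, and computes Forster resonance energy transfer
    (FRET) rate networks between chlorophylls from Qy transition dipoles
    anchored at the central magnesium atoms. Includes lifetime-thresholded
    network filtering, pigment census tables, stromal/lumenal layer
    classification, carotenoid-chlorophyll contact maps, magnesium
    axial-ligand detection, polar-contact screening, a synthetic fixture
    generator with analytic ground truth, and an end-to-end pipeline with a
    comparison report against stored expectation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
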