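Package: sideroscan
Title: Siderophore Discovery from Untargeted LC-MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens untargeted LC-MS metabolomics data for iron-chelating
    siderophores. Candidate ferric complexes are detected in MS1 feature
    tables through the natural 54Fe/56Fe isotopologue signature and through
    exact-mass pairing of the metal-free (apo) species with its ferric
    complex; candidates are corroborated by annotating MS/MS spectra against
    a hydroxamate building-block library. The package also provides
    molecular-formula decomposition under ppm tolerance, spectrum hygiene
    (contaminant removal, windowed top-k peak filtering), feature-based
    MS/MS molecular networking with the modified cosine score, GraphML
    export for Cytoscape, and a fully specified synthetic LC-MS scenario
    generator with ground truth so the entire pipeline can be exercised
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
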