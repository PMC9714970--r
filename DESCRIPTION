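Package: bundlequant
Title: Quantitative Analysis of Hair-Cell Imaging, Audiometry and Cholesterol-Recognition Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the quantitative analyses used in studies of
    sensory hair-cell membrane biology: synthetic two-channel confocal z-stack
    phantoms with ground-truth compartment masks; adaptive-threshold
    segmentation and fluorescence quantification (bounding-box intensity
    summaries, total and recruited signal, stereocilium versus basolateral
    compartment enrichment); object-level morphometry (enlarged-lysosome calls
    by the strict >2 micrometre equivalent-diameter rule, hair-bundle
    length/width, cell counting); auditory-evoked-potential simulation,
    stimulus-locked averaging and per-frequency threshold estimation; and
    physicochemical-alphabet conserved-pattern derivation plus CRAC/CARC
    cholesterol-recognition motif scanning. A first-principles Fisher exact
    test, percent-of-control normalisation and a configuration-driven runner
    tie the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
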