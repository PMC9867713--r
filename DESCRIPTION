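Package: TJspatial
Title: Spatial Quantification of Tight-Junction Disruption and Fate
    Patterning in Pluripotent Stem Cell Epithelia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how epithelial integrity shapes signaling and
    differentiation in human pluripotent stem cell monolayers.  Detects
    regions of disrupted tight-junction (ZO1) organization, bins nuclei
    into concentric distance rings around those regions, scores nuclear
    marker positivity (Huang/Otsu automatic thresholding, rolling-ball
    background subtraction, watershed nucleus splitting), fits
    positivity-versus-distance slopes, measures per-cell apical
    surfaces, profiles radial fate domains of circular micropatterned
    colonies, computes delta-delta-Ct relative quantification for
    RT-qPCR, and ships a seeded synthetic-image generator with planted
    ground truth so every stage is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Spatial, Visualization, SingleCell
RoxygenNote: 7.3.3
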