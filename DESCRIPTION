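Package: pemscope
Title: Spatial Quantification of Microglia-Pericyte Associations on Brain
    Microvasculature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify spatial associations between microglia and
    capillary pericytes from cell-coordinate exports and vessel centerline
    networks. Classifies capillary-associated microglia (CAM) and
    pericyte-associated microglia (PEM) by nucleus/soma center distance
    criteria, tests observed PEM proportions against a Monte-Carlo chance
    null with an analytic Poisson oracle, assigns branch orders on the
    vascular tree and measures vessel width at cell landmarks, tracks PEM
    retention, gain and loss across longitudinal imaging days, and
    quantifies marker intensity in expanded pericyte ROIs. A synthetic
    microvascular scene generator with configurable cell placement,
    vessel dilation at landmarks and time-series dynamics provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
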