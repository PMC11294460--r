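Package: junctionscape
Title: Spatial Quantification of Vesicles, Exocytosis and Cell Migration
    Relative to Endothelial Junction Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify where chemokine-containing vesicles,
    exocytosis events and transmigrating leukocytes sit relative to the
    junction topology of an endothelial monolayer. Builds a junction graph
    (bicellular edges, multicellular vertices) from a labeled monolayer
    image, measures Euclidean and along-junction distances to the nearest
    multicellular vertex, pairs two-channel spot detections at a distance
    threshold, extracts junction intensity decay profiles, scores cell
    tracks for straightness and arrest, and applies the accompanying
    normality-gated two-group testing scheme. A synthetic-monolayer
    generator with planted ground truth (Voronoi geometry, distance-decaying
    point patterns, planted colocalization fractions, persistent
    random-walk tracks) makes every stage verifiable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
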