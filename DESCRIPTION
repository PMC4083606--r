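Package: groovegeom
Title: Spline Geometry of Alpha-Helix Pairs in MHC Binding Grooves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric analysis of alpha-helix pairs over conformational
    trajectories. Each helix is assigned a local reference frame by principal
    component analysis of its C-alpha trace, and its overall shape is
    represented by a single-segment polynomial spline fitted by least squares
    in the two principal planes. From a pair of such splines the package
    computes interhelical distance profiles along rulings and the area of the
    triangulated ruled surface spanned between the helices, tracks these
    quantities frame by frame across a multi-model PDB trajectory, and
    summarises them (boxplot statistics, time-averaged areas, percent changes
    across polynomial degrees). A synthetic helix-pair trajectory generator
    with known ground-truth geometry supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
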