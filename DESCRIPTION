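Package: gridframes
Title: Reference-Frame Analysis of Grid-Cell Recordings on a Movable Platform
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for analysing the spatial firing geometry of medial
    entorhinal grid cells recorded while a square foraging platform is rotated
    or translated inside a cue-rich room. Covers speed-filtered occupancy and
    firing-rate maps, spatial auto- and crosscorrelograms, grid orientation,
    scale, elliptical distortion and gridness scoring with a bootstrap
    seven-criterion grid-cell classifier, decomposition of each grid's
    rotation and phase shift against room, physical-platform and geometric
    (square-symmetry) reference frames including the closed-form phase algebra
    for half-platform translations, pairwise geometric-coupling statistics
    with randomized controls, and 60-degree-symmetric circular statistics.
    Includes a synthetic-session generator (foraging trajectories,
    inhomogeneous-Poisson grid and boundary cells, configurable anchoring
    policies) so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
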