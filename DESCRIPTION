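Package: wormloop
Title: Quantitative Phenotyping of Nematode Exploratory Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Caenorhabditis elegans exploratory
    behaviour from multi-worm tracker centroid trajectories: signed curving
    rates (degrees per millimetre of advancement) with fixed-time and
    fixed-distance summaries, fractal coarse-grained path statistics
    (L-delta over L0 ratio curves and cohort median-of-log summaries),
    detection of loopy track segments and classification of circular
    locomotion (strong/mild/normal), head-bend kinematics from
    centroid/terminal-bulb/nose-tip landmarks, and quantification of GFP
    photobleach-and-recovery experiments (background correction, per-animal
    rate of change, control-normalised recovery ratio, puncta summaries).
    Includes a correlated-random-walk simulator with loopy locomotion
    bouts, an asymmetric head-wave generator, and a fluorescence-record
    generator so every analysis stage can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
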