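Package: cilquant
Title: Quantification of Contact Inhibition of Locomotion and Ratiometric
    FRET Boundary Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify contact inhibition of locomotion (CIL) and
    membrane-localized Rac1 biosensor activity in migrating cells. Computes
    single-cell directionality ratios and tissue-closure progress from
    manually tracked trajectories, signed collision angles and velocity
    ratios from annotated cell-cell collisions with circular statistics
    (mean angle, resultant length, Rayleigh test) and rule-based CIL
    classification, and ratiometric YFP/CFP FRET image statistics via
    radial membrane segmentation: 360-point perimeter intensity profiles,
    kymographs, and threshold-based high-activity boundary fractions. A
    synthetic-data generator (persistent random walks, scripted collisions,
    rendered two-channel ring-cell image stacks with exact ground truth)
    makes every stage testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
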