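Package: ampcal
Title: Calibration of Amplicon-Predicted Microbiome Functional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a per-molecular-function linear mapping from
    16S-amplicon-predicted functional profiles (e.g. PICRUSt-style KEGG
    Orthology tables) to shotgun-WGS-derived functional profiles using a
    small number of paired samples, and applies it to calibrate large
    batches of amplicon-only profiles to WGS-equivalent resolution.
    Includes the evaluation machinery used to assess such calibration
    (Bray-Curtis dissimilarity, paired and within-group distance
    summaries, principal coordinates analysis, PERMANOVA effect size,
    nearest-profile classification with confusion-matrix metrics), a
    seeded synthetic generator of paired WGS/amplicon profile tables
    with known ground-truth distortion, an experiment driver for
    training-set-size curves, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
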