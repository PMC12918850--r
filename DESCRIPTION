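Package: filamentr
Title: Amyloid Filament Fold Comparison and Fibrillization Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares amyloid protofilament folds by backbone RMSD over all
    contiguous sliding windows with per-window optimal (Kabsch)
    superposition, summarised as a localized RMSD and visualised as
    triangular heat-maps; ranks a query fold against a fold library.
    Builds synthetic helical filaments with specified rise, twist or
    crossover distance and recovers helical parameters from coordinates.
    Analyses Thioflavin T fibrillization time courses: background
    subtraction, Gompertz fitting by Levenberg-Marquardt least squares,
    quality-control filtering, apparent elongation rates and aggregation
    propensities, with a seeded simulator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
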