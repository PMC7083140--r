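Package: myoslice
Title: Structure-Function Analysis of Living Myocardial Slice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cardiomyocyte t-system remodeling from 3D
    membrane-stained confocal stacks (mean intracellular distance to the
    nearest t-tubule via an anisotropy-aware 3D Euclidean distance
    transform), extracts twitch kinetics and the force-frequency
    relationship from paced force recordings of myocardial slices,
    measures myocyte orientation disarray and sarcomere length in 2D tile
    scans, and relates structure, protein expression and function through
    linear and interaction regression models.  A synthetic-data module
    generates membrane phantoms, myocyte mosaics, striation patterns,
    force traces and cohort tables with known ground truth so that the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
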