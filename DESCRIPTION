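Package: septime
Title: Standardized Expression Profiles for Two-Group Developmental Time
    Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of factorial time-course RNA-seq experiments that
    contrast two groups of accessions (e.g. domesticated versus wild
    germplasm) across a shared developmental time grid. Counts are
    filtered for consistent expression, normalized to counts per million,
    and summarized per gene and accession as a standardized expression
    profile (SEP): the vector of time-point means rescaled to mean 0 and
    standard deviation 1. On top of the SEPs the package provides
    negative-binomial tendency classification between neighboring time
    points, pointwise group comparison with FDR control, accession
    clustering from mean SEP distances, detection of peak-shift patterns
    such as "D10W30" (peak at 10 DAA in one group, 30 DAA in the other),
    Fisher-exact GO enrichment, and distance/correlation-thresholded gene
    network estimation with transcription-factor imputation. A
    negative-binomial simulator with planted profile archetypes supplies
    ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
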