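Package: yeastclim
Title: Climate-Envelope Modelling of Wild Yeast Distributions from Oak Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the climate envelope of wild Saccharomyces
    yeasts from presence/absence surveys of oak trees. Fits weighted binomial
    generalized linear models of per-tree isolation frequency by iteratively
    reweighted least squares, simplifies models stepwise by deviance-based
    likelihood-ratio tests, derives optimum and occurrence summer-temperature
    (Tmax) envelopes from fitted response curves, shifts envelopes between
    species using laboratory growth-temperature offsets, and validates
    predicted ranges against worldwide strain collections using single-pixel
    raster extraction and great-circle distance to the nearest in-range cell.
    Includes a synthetic-data generator emulating the survey design, raster,
    and strain tables so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
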