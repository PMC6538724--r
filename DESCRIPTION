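Package: nlvuptake
Title: Probabilistic Modelling of Nanoparticle Uptake by Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the cell-to-cell heterogeneity of
    nanoparticle uptake by endocytosis. Implements the gamma-Poisson
    (negative binomial) model of nanoparticle-loaded vesicle (NLV) counts
    per cell, in which endosome formation is a spatial Poisson process
    proportional to cell area and rare particle capture thins that process;
    an event-level mechanistic simulator of coupled endosome formation and
    particle arrival; a seeded generator of CellProfiler-style per-cell and
    per-vesicle measurement tables; the calibration pipeline that estimates
    the uptake rate constant lambda from mean NLV counts versus the
    dose-time product; and DNA-content (G1/G2) gating with area-normalised
    Kolmogorov-Smirnov comparisons of per-cell uptake.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
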