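Package: chronoprot
Title: Time-of-Day Protein Interactomics from Affinity-Purification
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling time-of-day-specific protein interactors
    from affinity-purification mass-spectrometry (APMS) spectral counts:
    negative-control subtraction, replicate evidence filtering, parsimony
    grouping of shared peptide evidence, per-bait and pooled timepoint
    classification, and hypergeometric term enrichment. Companion circadian
    analyses include Fourier-seeded nonlinear least-squares (FFT-NLLS)
    period and acrophase estimation for luciferase reporter traces,
    Rayleigh circular statistics, entrainment resynchronization testing,
    western-blot densitometry and dual-luciferase normalization, and
    affine-gap global protein alignment with EMBOSS-needle semantics.
    A synthetic-data module generates every input class with known ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
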