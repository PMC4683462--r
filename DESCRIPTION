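Package: avigamut
Title: Colour-Gamut Analysis of Avifaunas in Avian Tetrahedral Colour Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the plumage colour gamut of a bird assemblage from
    reflectance spectra. Models tetrachromatic cone quantum catches under an
    ideal flat irradiance for ultraviolet- or violet-sensitive avian visual
    systems, embeds relative catches in the tetrahedral colour space of
    birds, and measures occupied colour space by convex-hull volume and
    overlap and by discrete chromatic-locus occupancy on a regular 3D grid.
    Assigns spectra to colour-production mechanisms (melanin, carotenoid,
    psittacofulvin, structural, and pigment-structure combinations) from
    spectral shape, and compares colour diversity between sexes and between
    taxonomic orders with species-level bootstrap resampling. Includes a
    parametric generator of labelled synthetic avifaunas so that the whole
    pipeline is testable without measured museum spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    signal,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
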