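Package: tmtproc
Title: Complementary Ion Quantification for TMTpro Multiplexed Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interference-free multiplexed proteome quantification
    from TMTpro complementary (balancer-peptide) ions. Encodes the isotopologue
    chemistry of the 18 TMTpro labels and their collapse into 9 distinguishable
    complement channels, predicts the complement-ion cluster m/z grid for a
    peptide-spectrum match, extracts observed cluster intensities from
    centroided MS2 spectra, and deconvolves channel abundances by solving the
    overdetermined linear system formed by tag isotopic impurities convolved
    with the peptide isotope envelope. Includes a synthetic two-proteome
    interference simulator with Poisson ion statistics and Orbitrap-style peak
    coalescence so every stage is testable without instrument data, plus
    downstream time-course analysis: razor peptide-to-protein assignment,
    anchor (mitochondrial-style) normalization, median protein roll-up,
    hierarchical k-means trajectory clustering, and fold-change summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mzR,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
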