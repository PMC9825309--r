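Package: diasimr
Title: Simulation of Data-Independent Acquisition LC-MS/MS Proteomics Data with Known Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic data-independent acquisition (DIA) bottom-up
    proteomics LC-MS/MS runs as standards-compliant mzML files with fully known
    peptide precursor and fragment content. Chromatographic elution is modelled
    with exponentially modified Gaussian profiles, precursor isotope envelopes
    are computed from elemental compositions, and DIA isolation-window duty
    cycles (fixed-width, variable, overlapping or staggered) schedule the scan
    events. Multi-group replicate study designs with configurable between- and
    within-group abundance variation and group- or sample-wise missingness are
    expanded into per-sample runs, optionally contaminated with decoy species
    from NIST .msp spectral libraries. A naive extracted-ion-chromatogram
    quantifier and fold-change recovery report support benchmarking of
    quantitative accuracy against the simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
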