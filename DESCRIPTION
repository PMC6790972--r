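Package: nitrosponge
Title: Nitrification, Carbon Fixation and Symbiont Quantification for Sponge Holobionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying the activity of ammonia-oxidizing
    archaeal symbionts in marine sponges. Estimates gross nitrification by
    15N isotope pool dilution and net dissolved-inorganic-nitrogen fluxes from
    incubation time series, converts 13C-bicarbonate tracer enrichment of
    sponge tissue into inorganic carbon fixation rates and fits the
    nitrification-to-fixation (N:C) coupling, performs absolute symbiont
    quantification from qPCR standard curves and relative quantification from
    FISH counts with derivation of cell-specific ammonia-oxidation rates, and
    provides comparative-genomic (length-weighted AAI, fragment-based ANI,
    exclusive shared gene families) and metaproteomic (NSAF) quantifications.
    Seeded synthetic-data generators reproduce the statistical structure of
    every input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
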