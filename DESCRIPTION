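Package: rdnadrift
Title: Simulation and Analysis of Ribosomal DNA Copy-Number Dynamics in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying copy-number dynamics of the tandemly repeated
    ribosomal DNA (rDNA) array on yeast chromosome XII across long-term
    evolution experiments. Provides a synthetic-data generator (reference
    repeat unit, tandem arrays with planted variants, long reads, short-read
    pileups, pulsed-field gel lane profiles, DNA-content histograms, and
    replicate copy-number trajectories), pulsed-field gel densitometry with
    ladder calibration and copy-number estimation, a bin-split long-read
    structural-variant caller over the circular repeat unit, naive per-position
    variant-frequency tallying on collapsed-unit coordinates, and generation
    accounting with replicate drift analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    zoo,
    signal,
    stats,
    utils,
    methods,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
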