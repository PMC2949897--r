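Package: snptracks
Title: Signal Filtering and Track Visualization for Pooling-Based Genome-Wide Association Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for noisy whole-genome association signals, with an
    emphasis on DNA-pooling designs. Computes relative allele signal (RAS)
    values from pooled two-channel SNP-array intensities, signed mean-RAS
    differences between cases and controls, per-SNP Welch t statistics and
    rank values; reads association result tables from configurable
    delimited-text dialects (GenePool, PLINK, EIGENSTRAT style) via INI
    presets; applies chained height filters (logarithmic enhancement,
    best-of-window sliding mean, cutoff-and-stretch) to per-chromosome
    score tracks; renders deterministic per-chromosome track bitmaps,
    Manhattan plots and Q-Q plots with genomic-control lambda correction
    for 2-df chi-square p-values; and simulates pooled intensity matrices
    and score tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
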