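Package: trackkit
Title: Composable Genome Track Visualization with Hi-C Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A composable toolkit for genome track figures in which data-bound
    track elements (signal histograms, gene annotation, interaction arcs,
    Hi-C contact matrices and derived analytic profiles) are combined into
    frames with a ggplot2-style "+" algebra, mirrored by a chained command
    line interface. Includes region-indexed readers for bedGraph, BED, GTF,
    BEDPE/pairs, SNP tables and HiC-Pro sparse contact matrices; built-in
    Hi-C analytics (virtual 4C, directionality index, insulation score,
    per-distance z-score differential matrices); an off-diagonal joint 2D
    view; browser-style navigation (goto/zoom/slide); and a region-bound
    data-fetch API so figures and the exact data behind them stay coupled.
    A seeded fixture generator produces every supported input format with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    grid,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
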