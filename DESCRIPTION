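Package: bisquer
Title: Bisulfite Conversion Quality Evaluation from Multiplex qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies genomic and bisulfite-converted DNA from multiplex
    TaqMan qPCR cycle-threshold (Ct) data and computes the three key quality
    metrics of a bisulfite conversion step: conversion efficiency, degradation
    level, and recovery. Standard curves calibrated on a genomic DNA dilution
    series quantify the cytosine-containing (short-C) and long cytosine-free
    amplicons; a transforming equation fitted on synthetic C/T indicator
    oligonucleotides converts short-T Ct values onto the short-C scale so that
    converted molecules can be quantified against the same curve. Also
    included: in-silico bisulfite conversion and exhaustive scanning for
    cytosine-free primers and single-site C/T discrimination probes, an
    in-silico PCR amplicon extractor, a molecule-level simulator of the whole
    conversion plus multiplex qPCR experiment with closed-form expected
    metrics for parameter-recovery testing, and the kit-comparison statistical
    cascade (Shapiro-Wilk/Levene gated one-way ANOVA, Welch ANOVA or
    Kruskal-Wallis with matching post-hoc tests including Games-Howell).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    withr,
    car,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
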