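Package: methqc
Title: Quality Control and Primary Analysis of Illumina Infinium
    Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated quality control and primary analysis for Illumina
    Infinium HumanMethylation27/HumanMethylation450 BeadChip experiments
    exported from the GenomeStudio Methylation Module. Parses the Sample
    table, Control probe profile and Average Beta table exports, scores the
    eight internal control-probe categories as percentage of background on
    signal, summarizes detection p-values and removes low-performance
    samples, quantile-normalizes methylated and unmethylated probe
    intensities at the probe level, computes Beta- and M-values, assesses
    sample similarity by principal component analysis and hierarchical
    clustering, and renders a printable QC report together with
    machine-readable statistics exports. Ships a synthetic-data generator
    that emulates GenomeStudio exports with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
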