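Package: puritrace
Title: Electropherogram-Based Purity Screening of Algal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether an algal culture is unialgal from a single Sanger
    sequencing electropherogram. Implements per-base Phred quality-value (QV)
    trimming of reads (a 5' window scan after an initial skip and a 3' scan
    that starts 350 bases into the retained sequence), a sub-QV20-fraction
    purity statistic with a strict one-percent cutoff, ABIF (.ab1) trace
    reading and writing, paired FASTA/QUAL I/O, degenerate-primer in-silico
    PCR for the eukaryotic V4 18S rDNA primer pair, and a mixed-template
    chromatogram simulator that provides ground truth for validating the
    classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
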