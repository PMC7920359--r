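Package: bcbalance
Title: Color-Balance Analysis and Selection of Sequencing Barcode Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for checking and designing pools of sequencing index
    barcodes for platforms that read all DNA nanoballs synchronously per
    cycle (MGISEQ-2000 / DNBSEQ-G400). Computes weighted per-position
    nucleotide fractions for a pooled barcode set, classifies each
    position against configurable strong/lite balance corridors,
    analyzes pairwise Hamming distances and mismatch-tolerant
    decodability, simulates barcode reads under substitution error
    models, and searches a candidate pool for barcode additions that
    keep a set balanced. Panels are plain tibbles read from TSV or
    FASTA; results carry tidy() and glance() methods and ggplot2
    autoplot() figures.
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
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
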