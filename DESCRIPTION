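Package: annodiff
Title: Compare Two Annotations of the Same Prokaryotic Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-references two annotation releases of the same bacterial
    genome (for example a GenBank record and its RefSeq re-annotation),
    matches loci through the old_locus_tag attribute, classifies
    strand-aware start/stop coordinate shifts and reading-frame changes,
    detects gene pairs whose overlap status flips between releases, tests
    COG functional categories for overrepresentation among shifted genes
    with a one-tailed Fisher's exact test, and quantifies how paired
    RNA-seq log2 fold-change results computed against either reference
    agree. Ships a synthetic annotation-pair generator with a planted
    ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    jsonlite,
    methods,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
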