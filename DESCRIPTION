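Package: overlapfilter
Title: Complete-Overlap Quality Filtering for Fully Overlapping Paired-End Amplicon Reads
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality filtering for Illumina paired-end amplicon libraries in which both
    mates span the entire insert, such as 16S rRNA V6 libraries sequenced with 100-cycle
    paired-end runs. Implements the complete-overlap filter, which demands 100% agreement
    between the two reads across the region between the primer sites and so removes
    nearly all random sequencing errors without consulting machine-reported quality
    scores. Also provides the two classical Q-score based filters it is usually compared
    against (run-length quality trimming with a length ratio test, and B-tail removal
    with a first-half Q30 criterion), inline-barcode demultiplexing with degenerate
    primer matching, greedy identity-threshold OTU clustering with equal-depth
    subsampling, a synthetic paired-read simulator with controllable error structure,
    and tidy reporting (pass-ratio tables, three-way Venn partitions of read fates,
    per-position mean quality curves, and information-retention arithmetic).
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
    purrr,
    readr,
    rlang,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
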