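Package: markswitch
Title: Calibrated DNA-Modification Calling and Mark-Switching Analysis for
    Bisulfite Assay Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for cytosine-modification panels
    measured by three bisulfite chemistries: conventional bisulfite sequencing
    (5mC+5hmC), Tet-assisted bisulfite sequencing (5hmC), and M.SssI-assisted
    bisulfite sequencing (5fC/5caC). Provides spike-in conversion-efficiency
    calibration, a binomial caller for low-abundance 5fC/5caC accounting for
    the M.SssI failure rate, tier and differential classification of per-site
    modification levels, pairwise switching quadrants and three-mark switch
    codes between cell classes, genomic-feature and chromatin-state enrichment
    of switching events, tissue-specific enhancer stratification by interval
    overlap, variable-site epigenetic trees, TET co-expression and median-split
    log-rank survival screens, and strand-specific non-CpG profiling. A
    ground-truthed synthetic-data generator emulates the full study design
    (two cell classes by multiple lines, assay chemistry with configurable
    efficiencies, overdispersed coverage, planted switching events, planted
    tissue-specific peaks, planted co-expressed and prognostic genes) so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    ape,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    Biostrings,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
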