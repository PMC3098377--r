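Package: islandscape
Title: CpG-Island Detection, ChIP Tag Profiling, and ZF-CxxC Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recruitment of ZF-CxxC domain proteins (such as
    the H3K36 demethylase KDM2A) to nonmethylated CpG islands. Implements
    sliding-window CpG-island prediction with GC content and observed/expected
    CpG statistics, ChIP-seq tag-density meta-profiles anchored on transcription
    start sites or length-scaled islands, percent-of-input and histone
    H3-normalized enrichment with a paired promoter-versus-body test, windowed
    Poisson peak calling with island-occupancy reporting, knockdown volcano
    analysis, allele-resolved bisulfite clone methylation calling with lollipop
    rendering and Fisher allele-enrichment tests, and 1:1 Langmuir
    surface-plasmon-resonance models with kinetic and steady-state dissociation
    constant estimation. A synthetic-data generator produces toy genomes,
    methylomes, ChIP tag tracks, bisulfite clones, sensorgrams, and expression
    matrices embodying the underlying biological model so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    S4Vectors,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
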