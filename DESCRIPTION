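Package: gbs3d
Title: Three-Enzyme Genotyping-by-Sequencing Protocol Design and Marker
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation toolkit for reduced-representation
    sequencing protocols built on multi-enzyme restriction digestion
    (three-enzyme "3D-GBS" designs and classic single-enzyme GBS). Performs
    in-silico digestion of reference genomes with IUPAC-ambiguous
    recognition sites and optional cytosine-methylation awareness, applies
    the adapter-compatibility and size-selection model to predict genome
    coverage, models per-fragment sequencing depth and genotype dropout as
    a Poisson read-allocation problem to optimize reads per sample and
    multiplexing, and computes marker-distribution diagnostics (variant
    filtering, SNP densities and gap inventories on physical and genetic
    maps, diversity statistics, identity-by-state distances) used to
    validate a protocol. Ships synthetic generators for genomes,
    methylation tracks, genetic maps, VCFs and FASTQ so every analysis is
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
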