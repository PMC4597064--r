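Package: clonediv
Title: Integrative Multi-Omic Clonality Analysis of Tumor Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joins somatic DNA mutations from whole-exome sequencing with
    RNA-expressed variants, transcript quantification, gene-level read
    counts, copy-number segments and Illumina 450K promoter methylation
    into one integrated relation per tumor sample, then quantifies clonal
    architecture with an abundance-weighted Shannon diversity index and a
    copy-number-weighted Gaussian kernel density of variant allele
    frequencies with a two-stage direct plug-in bandwidth.  Includes
    paired presentation/relapse sample comparison, tumor-suppressor-gene
    silencing tables, three standard visualizations with machine-readable
    data exports, a seeded synthetic multi-omic data generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    KernSmooth,
    vcfR,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
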