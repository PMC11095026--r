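Package: rmsim
Title: Simulation and Quantification of Reduced Metagenome Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates restriction-digest reduced-representation sequencing
    (ddRADseq-style) libraries from mixed microbial communities: genomes are
    digested in silico with IUPAC-degenerate enzyme motifs under a partial
    digestion probability model, fragments pass through a Gaussian (or
    custom) size-selection envelope, and a fixed read budget is converted
    into paired-end FASTQ with sampled base qualities and Phred-driven
    substitution errors. Companion estimators recover the enzyme cut
    efficiency from encompassment count ratios and recover relative
    taxonomic abundances from per-length read-depth ratios (fixed length
    taxonomic ratios, FLTR), with mean- and median-depth baselines for
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
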