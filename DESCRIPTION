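Package: codonscan
Title: Codon-Aware Analysis of Saturation Mutagenesis Screens
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled saturation-mutagenesis amplicon
    screens in which a short coding region (such as the RNA polymerase II
    trigger loop) is mutagenized codon-by-codon and phenotyped by deep
    sequencing under many growth conditions. Provides a synthetic screen
    generator (library composition, pooled selection, sequencing error and
    PCR template switching), a codon-unit dynamic-programming variant caller
    with perfect-flank paired-end merging, log-ratio phenotypic and fitness
    scoring with read-count filters, spike-in template-switching quality
    control, lethality-cutoff calibration, and mutant-class discovery by
    hierarchical clustering of phenotype profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
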