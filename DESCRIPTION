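Package: svjunctions
Title: Structural Variant Junction Microhomology and Templated-Insertion
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of structural variant (SV) breakpoint junctions from
    single-molecule capture sequencing of common fragile sites. Implements
    molecule-level SV filtering and adjusted target coverage, junction
    microhomology/insertion characterization from dual-coordinate
    breakpoints, local insertion-template discovery and classification
    (foldback, palindrome, cross-junction, strand-switching, expansion)
    diagnostic of theta-mediated end joining, binomial template-enrichment
    statistics against the local random-match expectation, and
    negative-binomial SV-frequency comparison between experimental groups
    with a coverage exposure offset. A synthetic-cohort generator plants
    junctions with known mechanism truth so that every analysis stage can
    be verified without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    MASS,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    optparse,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
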