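Package: insmech
Title: Reconstruction and Mechanistic Classification of Complex
    Chromosomal Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for resolving complex chromosomal insertions from
    array comparative genomic hybridization (aCGH) copy-number profiles
    and breakpoint-junction sequences. Annotates junctions with the
    standard feature taxonomy (microhomology, untemplated and templated
    insertions), segments probe-level log2 ratios into copy-number
    calls and per-chromosome pattern strings including DUP-TRP/INV-DUP
    recognition, reconstructs derivative chromosomes as
    copy-number-consistent walks through a breakpoint graph with
    minimal hypothetical-junction inference, classifies the generative
    mechanism (end joining versus replicative FoSTeS/MMBIR
    chromoanasynthesis), and predicts meiotic transmission outcomes for
    parental balanced and unbalanced insertions. Includes a seeded
    simulator of replicative template-switch chains and end-joining
    exchanges that emulates the assays the pipeline consumes, and
    machine-readable toy-coordinate fixtures for nine resolved clinical
    cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
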