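Package: targetasm
Title: Target-Guided de Bruijn Graph Assembly of Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles Illumina-style short reads guided by user-supplied
    nucleotide or protein target sequences. Builds primary and secondary de
    Bruijn graphs from the reads, locates seed k-mers that align well to each
    target, extends seeds into paths under an affine-gap drop-off alignment
    (translated on the fly against protein targets using BLOSUM62), filters
    graph connections unsupported by reads and read pairs, and reports an
    assembly graph in GFA 1.0 together with ranked well-supported sequence
    variants. Includes a read simulator with controllable haplotypes,
    substitution errors, strand-biased errors and contamination so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
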