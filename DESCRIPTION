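Package: linafunnel
Title: Candidate-Gene Funnel for Bacterial Ice Nucleation Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the inference chain used to identify a PKS-NRPS
    biosynthetic gene cluster underlying bacterial ice nucleation activity:
    cumulative ice-nucleation spectrum estimation from droplet-freezing
    dilution assays, clade-unique gene filtering over a Roary-style
    pan-genome presence/absence matrix, TPM-based expression filtering,
    signature-domain tagging of biosynthetic core genes, and variant
    recurrence ranking across UV-mutagenesis screens. A seeded synthetic-data
    generator produces every pipeline input, including a replay fixture whose
    planted truth reproduces the funnel's published stage structure, so the
    full analysis can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    yaml,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
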