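Package: pirnanet
Title: Inference of piRNA Ping-Pong and Phased-Biogenesis Networks from
    Small-RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect the piRNA ping-pong amplification signature
    (10-nt 5'-overlap z-score with 1U/10A base biases) on transcripts, to
    classify transcripts by the genomic multiplicity of their ping-pong
    piRNAs, to infer trigger/responder/trail phased piRNA biogenesis events
    through mismatch-tolerant reverse-complement target search, and to
    assemble the resulting transcript regulatory networks (shared-repeat
    ping-pong groups and directed snetDNA targeting graphs). Includes a
    seeded synthetic-data generator that plants ping-pong pairs, repeat
    families and trigger events with a ground-truth manifest so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
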