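Package: cardiorelevance
Title: Variant Relevance Discovery for Inherited Cardiopathies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates VCF variants against transcript models of cardiopathy
    gene panels, classifies clinical relevance with a four-criterion rule set
    (HIGH impact, disruptive protein change, loss-of-function or
    nonsense-mediated decay, critical amino-acid change), attaches structural
    and functional context from a five-dimension cardiopathy knowledge graph,
    and evaluates concordance against ClinVar-style clinical labels.
    Ships seeded synthetic-data generators so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    vcfR,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
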