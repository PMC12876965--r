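Package: spacemir
Title: Multi-Tissue miRNA Spaceflight Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-tissue small-RNA sequencing studies of
    spaceflight-exposed mice and matched ground controls. Provides detection
    filtering and reads-per-million normalization of miRNA count matrices,
    rank-based differential expression with median fold changes and Cohen's d
    deregulation calls, principal variance component analysis (PVCA) of design
    factors, directional set logic to attribute deregulation to spaceflight,
    housing, or age, miRNA-mRNA target integration on weighted
    context++-style score tables, overrepresentation and pre-ranked set
    enrichment, and a negative-binomial synthetic-data generator with planted,
    recorded effects for end-to-end recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
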