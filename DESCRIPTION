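Package: codoncontext
Title: Codon Usage Bias and 3' Codon-Context Analysis of Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage bias and 3' codon-pair
    context bias in sets of open reading frames stratified by expression level,
    GC content and length. Implements relative synonymous codon usage (RSCU),
    RPKM-based expression grouping schemes (per-condition, highest-value,
    average-value and ribosomal reference groups), RSCU ratio maps with a
    0.9-1.1 similarity band, adjacent codon-pair contingency tables with
    adjusted residuals and a +/-3 significance rule, top-k preferred/avoided
    codon pairs, and differential display maps comparing groups. Ships a
    seeded synthetic generator of in-frame coding sequences (first-order
    Markov codon chains with optional codon-pair coupling and GC targeting)
    and four-condition expression matrices, so every stage of the pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
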