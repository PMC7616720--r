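Package: splicevolver
Title: In Silico Directed Evolution of TDP-43-Regulated Cryptic Splicing Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs de novo cryptic splicing events (cassette exons,
    alternative 5'/3' splice sites, intron retention) inside protein-coding
    sequences using only synonymous mutations. A directed-evolution engine
    scores candidate sequences with a pluggable per-nucleotide splice-site
    predictor (a deterministic position-weight surrogate ships with the
    package; an adapter contract supports external deep-learning models)
    against a user-specified ideal splicing profile. Rational-design helpers
    place competitor splice sites, recode polypyrimidine tracts
    synonymously, and build UG-rich TDP-43 binding regions. A companion
    quantifier computes percent-spliced-in from splice-junction count
    tables, classifies multi-cryptic-exon isoforms from long-read junction
    chains, and applies reading-frame and nonsense-mediated-decay logic to
    call productive transcripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
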