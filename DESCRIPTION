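Package: paraclave
Title: Paralog Profiling and Convergent-Adaptation Screening in Prokaryotes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline linking prokaryotic gene duplication to
    environmental adaptation. Calls paralogs by all-vs-all within-proteome
    local alignment at a strict identity threshold, profiles COG functional
    categories of paralogs versus persistent singletons, runs background-aware
    Gene Ontology overrepresentation analysis with Bonferroni control,
    enumerates inclusion-maximal biclusters (BiMax) of species versus
    overrepresented terms, scores cluster homogeneity with Wang-style
    edge-weighted semantic similarity, estimates alignment-free phylogenetic
    distances from shortest-unique-substring statistics with Jukes-Cantor
    correction, and screens for biclusters combining high functional
    similarity with large evolutionary distance as candidates for convergent
    adaptation. Ships seed-deterministic synthetic-data generators for every
    input so the whole analysis is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
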