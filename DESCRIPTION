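Package: gocooc
Title: Functional Dissimilarity of Gene Ontology Terms from Annotation
    and Interactome Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species-specific metrics of Gene Ontology (GO) term functional
    dissimilarity inferred from biological data rather than from the
    structure of the ontology graph. Two low-tail hypergeometric
    probabilities are computed for a pair of GO terms: one from the
    co-occurrence of the terms in protein annotations (annotation
    probability, AP) and one from their co-occurrence across the edges of a
    protein-protein interaction network (interaction probability, IP).
    Term pairs that co-occur less often than expected by chance are flagged
    as functionally dissimilar, a signal useful for screening moonlighting
    protein candidates. The package parses OBO ontologies, GAF annotation
    files and PSI-MITAB interaction files, propagates annotations over the
    ontology DAG under the true-path rule, builds filtered binary
    interactomes, and reports Jaccard and Cohen's kappa agreement
    statistics plus Monte-Carlo power of the co-occurrence test. A
    deterministic fixture generator emits small, valid input triples with
    planted co-occurrence structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
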