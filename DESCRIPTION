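Package: tmatriad
Title: Semantic Hypothesis Testing for Tissue-Microarray Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents tissue-microarray (TMA) experiment data as RDF
    triples under a declarative relational-to-RDF mapping, compiles triadic
    biological hypotheses ("in condition A, entity B correlates with entity
    C") into four conjunctive count queries over the triple graph, assembles
    the resulting 2x2 contingency table, and decides the hypothesis by
    Fisher's exact test. Includes complementary value-set reasoning over
    context-dependent controlled vocabularies, marker-mediated integration
    of DNA-microarray probes with TMA antibodies, a synthetic TMA data
    generator with a configurable marker-phenotype odds ratio, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
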