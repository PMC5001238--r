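Package: phenoscreen
Title: Phenotype-Profile Semantic Similarity Screening for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks candidate drugs against a disease by comparing weighted
    mouse-phenotype profiles. Disease profiles are built from disease-associated
    genes and gene-phenotype annotations; drug profiles from confidence-scored
    drug-target links. Profiles are compared with Resnik information-content
    semantic similarity under a phenotype ontology (best-match average,
    symmetrized), and ranked lists are evaluated against labeled drug sets with
    median percentile ranks, paired t-tests, precision-recall curves and
    average precision. Includes a seeded synthetic-data generator (ontology,
    annotation corpus, disease genes, drug-target tables with planted
    positives) so the whole pipeline runs without external downloads, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
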