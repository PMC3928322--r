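Package: goforge
Title: Ortholog-Augmented Gene Ontology Annotation and Gene-Set Enrichment Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for augmenting a human Gene Ontology annotation corpus with
    developmental annotations transferred from mouse through strict one-to-one
    orthology, under explicit evidence-code policies. Parses OBO ontologies and
    GAF 2.0 annotation files, propagates annotations to ancestor terms along
    is_a and part_of relations (the true path rule), builds GMT gene-set
    collections with effective-size filtering, runs a self-contained GSEA-style
    enrichment analysis (two-class phenotype permutation and pre-ranked gene
    permutation), and quantitatively compares the enrichment results obtained
    with an augmented versus a baseline gene-set collection (unique/common
    partitioning, significance tallies, one-sided Fisher tests, newly
    significant term accounting). Includes seeded synthetic-data generators for
    every input format so the full pipeline is testable without downloads.
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
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
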