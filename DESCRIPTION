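Package: famseg
Title: Rare-Variant Segregation and Prioritisation in Multiplex Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Family-based prioritisation of rare damaging variants in
    highly multiplex pedigrees. Classifies family members into autistic-trait
    subgroups from questionnaire scores, filters rare damaging variants in
    constrained genes, applies diagnosis-based and trait-based within-family
    segregation rules and a five-criterion trio de novo filter, annotates hit
    genes with evidence tiers from curated gene lists, and tests carrier
    enrichment with an uncorrected 2x2 chi-square statistic. Ships a seeded
    synthetic cohort generator (pedigrees, genotypes, annotations and truth
    tables) so every stage is testable without access to controlled genomes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
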