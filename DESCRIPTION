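Package: varranker
Title: Phenotype-Aware Prioritization of Causative Variants in Rare-Disease Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease-causing single-nucleotide variants and
    small indels from annotated exome data for rare Mendelian disorders.
    Variants are filtered by deleteriousness criteria (allele frequency and
    functional-consequence classes), gene-phenotype relevance is scored from
    free-text clinical keywords against per-source gene-description corpora
    with Okapi BM25 and the Robertson-Sparck-Jones weighted rank formula,
    and a random-forest classifier trained on a 94-column feature set
    (functional-prediction rank scores, weighted ACMG/AMP evidence, gene
    constraint metrics, inheritance patterns, genotype, phenotype-similarity
    scores) orders each patient's variants by disease-causing probability.
    Includes mutual-information feature selection, top-k and cumulative rank
    evaluation in variant, patient and gene modes, and a synthetic cohort and
    corpus generator for end-to-end testing without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
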