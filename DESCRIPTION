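Package: phenospan
Title: Extraction, Grounding and HPO Normalization of Continuous and
    Discontinuous Phenotype Mentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for recognizing phenotype mentions in short clinical
    observations and normalizing them to Human Phenotype Ontology (HPO)
    concepts. Supports mentions whose tokens are non-consecutive in the text
    (discontinuous entities represented as 2-3 character-offset fragments):
    reading and writing standoff annotations, converting annotations to and
    from linearized sequence-to-sequence targets, grounding generated mention
    text back to character offsets, dictionary-based candidate generation by
    cosine similarity with reranking, low-rank adapter merge arithmetic,
    stratified span-matching evaluation (exact, partial, disjoint-only,
    class-wise, normalization, combined), and a seeded synthetic corpus
    generator for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
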