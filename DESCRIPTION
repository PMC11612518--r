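Package: ssss
Title: Segmentation Synonym Sentence Synthesis for Clinical NER Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Data augmentation for Chinese clinical named-entity-recognition
    corpora by Segmentation Synonym Sentence Synthesis (SSSS): entity mentions
    are segmented into simple words, segments are replaced by near-synonyms
    drawn from a lexicon ranked by Levenshtein edit distance and optional
    embedding similarity, and the sentence is resynthesized with all entity
    spans re-projected. Includes lossless conversion between span-annotated
    JSON-lines records and character-level BIO tag files, strict entity-level
    precision/recall/F1 scoring with unknown/low/high training-frequency
    stratification, a deterministic gazetteer reference tagger, and a
    synthetic corpus generator so the whole augment-tag-evaluate loop is
    testable without restricted clinical data.
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
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
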