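Package: clinrank
Title: Clinical-Relevance Triage and Ranking of Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale search-engine core for precision-oncology
    literature triage. Reads PubMed-style abstracts, annotates gene,
    variant and drug mentions with lexicons and a rule grammar, trains
    query-independent cancer-relatedness, clinical-relevance and
    cancer-type classifiers (tf-idf word n-grams, chi-squared feature
    selection, linear SVM or random forest), composes the classifier
    outputs into a learning-free ranking score, and evaluates rankings
    with MAP, MRR, nDCG, restricted precision/recall at k and the ratio
    of mean relevant to mean irrelevant rank. A seeded synthetic-corpus
    generator provides class-conditional vocabularies, injected entity
    mentions and per-query relevance judgments so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    ranger,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
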