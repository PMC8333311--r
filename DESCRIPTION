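Package: genelit
Title: Gene Literature Mining: Disambiguation, Publication Trends, Topics
    and Review Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining gene mentions out of a biomedical publication
    corpus. Builds gene and disease synonym dictionaries, classifies synonyms
    as safe or unsafe with engineered ambiguity features and
    positive-unlabelled bagging, disambiguates candidate publications through
    weighted co-citation communities plus text classifiers, assembles per-gene
    yearly publication and citation series, forecasts them with a small
    recurrent encoder-decoder and scores genes by trendiness (the right-tail
    probability of the predicted-over-realised fold change within
    publication-volume bins), explains trends with non-negative matrix
    factorisation topic timelines, and recommends minimal sets of reviews that
    maximise PageRank-weighted coverage of a gene's literature. Includes
    synthetic-corpus generators with planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    randomForest,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr,
    mclust
Config/testthat/edition: 3
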