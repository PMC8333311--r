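test_that("corpus readers handle empty files and round-trip both formats", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), f)
  expect_equal(nrow(read_corpus(f, "jsonl")), 0)

  corpus <- toy_corpus(
    list(pub_id = "1", title = "Alpha study", abstract = "About things",
         keywords = c("kinase", "assay"), year = 1999L, is_review = TRUE,
         affiliations = c("Dept of X, BigCo Ltd, UK"), pharma_class = "big"),
    list(pub_id = "2", title = "Beta trial", year = 2005L, is_trial = TRUE),
    list(pub_id = "3", title = "Gamma notes", abstract = "", year = 2010L)
  )
  for (fmt in c("jsonl", "xml")) {
    path <- withr::local_tempfile()
    write_corpus(corpus, path, fmt)
    back <- read_corpus(path, fmt)
    expect_identical(as.data.frame(back), as.data.frame(corpus),
                     label = paste("round-trip", fmt))
  }
})

test_that("round-trip identity holds on randomly generated corpora", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    corpus <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      tibble::tibble(
        pub_id = paste0("R", rep, "_", i),
        title = paste(sample(letters, 5), collapse = " "),
        abstract = if (runif(1) < 0.3) "" else paste(sample(letters, 8), collapse = " "),
        keywords = list(if (runif(1) < 0.5) character() else sample(LETTERS, 2)),
        year = sample(1900:2020, 1),
        is_review = runif(1) < 0.3, is_trial = runif(1) < 0.2,
        affiliations = list(if (runif(1) < 0.5) character() else "Some Org, Somewhere"),
        pharma_class = sample(c("none", "big", "medium"), 1))
    }))
    fmt <- if (rep %% 2 == 0) "xml" else "jsonl"
    path <- withr::local_tempfile()
    write_corpus(corpus, path, fmt)
    expect_identical(as.data.frame(read_corpus(path, fmt)),
                     as.data.frame(corpus))
  }
})

test_that("a hand-written PubMed-style XML fixture parses field by field", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    "<PubmedArticleSet>",
    " <PubmedArticle><MedlineCitation><PMID>424242</PMID>",
    "  <Article><ArticleTitle>A review of orca biology</ArticleTitle>",
    "   <Abstract><AbstractText>Whales at sea.</AbstractText></Abstract>",
    "   <Journal><JournalIssue><PubDate><Year>2012</Year></PubDate></JournalIssue></Journal>",
    "   <PublicationTypeList><PublicationType>Journal Article</PublicationType>",
    "    <PublicationType>Review</PublicationType></PublicationTypeList>",
    "   <AffiliationInfo><Affiliation>Marine Institute</Affiliation></AffiliationInfo>",
    "  </Article>",
    "  <KeywordList><Keyword>cetacean</Keyword><Keyword>ecology</Keyword></KeywordList>",
    " </MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), path)
  corpus <- read_corpus(path, "xml")
  expect_equal(corpus$pub_id, "424242")
  expect_equal(corpus$title, "A review of orca biology")
  expect_equal(corpus$abstract, "Whales at sea.")
  expect_equal(corpus$year, 2012L)
  expect_true(corpus$is_review)
  expect_false(corpus$is_trial)
  expect_equal(corpus$keywords[[1]], c("cetacean", "ecology"))
  expect_equal(corpus$affiliations[[1]], "Marine Institute")
  expect_equal(corpus$pharma_class, "none")
})

test_that("malformed records error with the record index and field", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"pub_id":"1","year":2000}', '{"title":"no id","year":2001}'), path)
  expect_error(read_corpus(path, "jsonl"), "record 2.*pub_id")
})

test_that("citation graphs are restricted, deduplicated and self-loop free", {
  corpus <- toy_corpus(
    list(pub_id = "A", year = 2000L), list(pub_id = "B", year = 2001L),
    list(pub_id = "C", year = 2002L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path)
  expect_equal(nrow(build_citation_graph(path, corpus)), 0)

  writeLines(c("A\tB", "A\tB"), path)
  expect_equal(nrow(build_citation_graph(path, corpus)), 1)

  # 10 edges, 2 referencing unknown ids, 1 self-loop duplicate pair collapses
  writeLines(c("A\tB", "B\tC", "C\tA", "A\tC", "B\tA", "C\tB", "A\tB",
               "X\tA", "B\tZ", "C\tA"), path)
  g <- build_citation_graph(path, corpus)
  expect_equal(nrow(g), 6)  # 8 in-corpus lines minus 2 duplicates
  expect_true(all(g$citing %in% corpus$pub_id & g$cited %in% corpus$pub_id))

  writeLines(c("A\tB", "oops"), path)
  expect_error(build_citation_graph(path, corpus), "line 2")
})

test_that("affiliation tagging applies the big > medium precedence and is idempotent", {
  orgs <- tibble::tibble(name = c("BigCo", "MedCorp"),
                         size_class = c("big", "medium"))
  corpus <- toy_corpus(
    list(pub_id = "1", year = 2000L, affiliations = "Dept of X, BigCo Ltd, UK"),
    list(pub_id = "2", year = 2000L),
    list(pub_id = "3", year = 2000L, affiliations = "MedCorp Research Unit"),
    list(pub_id = "4", year = 2000L,
         affiliations = c("MedCorp Unit", "BigCo Campus")),
    list(pub_id = "5", year = 2000L, affiliations = "TheBigCoX building"))
  tagged <- tag_affiliations(corpus, orgs)
  expect_equal(tagged$pharma_class, c("big", "none", "medium", "big", "none"))
  expect_identical(tag_affiliations(tagged, orgs), tagged)
})
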