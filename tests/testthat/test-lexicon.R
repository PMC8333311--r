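gene_tables <- function() {
  list(
    tibble::tibble(symbol = c("TP53", "TP53", "INSR", "INS"),
                   synonym = c("p53", "Li Fraumeni syndrome",
                               "insulin receptor", "insulin")),
    tibble::tibble(symbol = c("NR2F2", "ACTR1A"),
                   synonym = c("ARP1", "ARP1"))
  )
}

test_that("disease-identical synonyms are removed and classes computed", {
  diseases <- build_disease_dictionary(tibble::tibble(
    term_id = c("D1", "D0"),
    names = list("Li Fraumeni syndrome", "Disease Root"),
    parents = list("D0", character())
  ))
  dict <- build_gene_dictionary(gene_tables(), disease_names = diseases)
  expect_false("li fraumeni syndrome" %in% tolower(dict$synonym))
  # 'insulin' is nested inside 'insulin receptor'
  expect_true(dict$is_nested[dict$synonym == "insulin"])
  expect_false(dict$is_nested[dict$synonym == "insulin receptor"])
  # 'ARP1' appears under two symbols
  expect_true(all(dict$is_promiscuous[dict$synonym == "ARP1"]))
  expect_equal(sum(dict$synonym == "ARP1"), 2)
  # symbols are included among their synonyms
  expect_true(all(c("TP53", "INSR", "INS") %in% dict$synonym))
  # short and english classes
  expect_true(all(dict$is_short[nchar(dict$synonym) < 3]))
  expect_true(dict$is_english[dict$synonym == "insulin"] == FALSE)
})

test_that("gene dictionary construction is order independent", {
  tabs <- gene_tables()
  a <- build_gene_dictionary(tabs)
  b <- build_gene_dictionary(rev(tabs))
  expect_identical(a, b)
})

test_that("comma-form disease names gain fully reversed variants", {
  dd <- build_disease_dictionary(tibble::tibble(
    term_id = c("R", "D1", "D2", "D3"),
    names = list("Disease Root", "Insipidus, Diabetes", "Plain Name",
                 "Severe, Acquired, Anemia"),
    parents = list(character(), "R", "R", "R")
  ))
  expect_true("Diabetes Insipidus" %in% dd$names[[which(dd$term_id == "D1")]])
  expect_equal(dd$names[[which(dd$term_id == "D2")]], "Plain Name")
  expect_true("Anemia Acquired Severe" %in% dd$names[[which(dd$term_id == "D3")]])
})

test_that("cyclic parent links are rejected", {
  expect_error(build_disease_dictionary(tibble::tibble(
    term_id = c("A", "B"), names = list("a", "b"),
    parents = list("B", "A"))), "cyclic")
})

test_that("character information content has its closed form", {
  expect_equal(genelit:::char_bits("", c(a = 0.5, total = 2)), 0)
  expect_equal(genelit:::char_bits("a", c(a = 0.5, total = 2)), 1.0)
  expect_equal(genelit:::char_bits("aa", c(a = 0.25, total = 4)), 4.0)
})

test_that("safety features capture asymmetric conditional probabilities", {
  # 'STAR'-like setting: the short synonym appears in many documents without
  # the long synonym, the long one rarely appears alone
  dict <- build_gene_dictionary(tibble::tibble(
    symbol = "STAR1",
    synonym = c("STAR", "Steroidogenic Acute Regulatory Protein")))
  docs <- c(
    lapply(1:8, function(i) list(pub_id = paste0("bg", i), year = 2000L,
                                 title = "a star is born tonight")),
    lapply(1:4, function(i) list(pub_id = paste0("g", i), year = 2000L,
      title = "STAR encodes the Steroidogenic Acute Regulatory Protein"))
  )
  corpus <- do.call(toy_corpus, docs)
  m <- find_candidates(corpus, dict)
  feats <- compute_safety_features(dict, corpus, m)
  star <- feats[feats$synonym == "STAR", ]
  long <- feats[feats$synonym != "STAR" & feats$symbol == "STAR1" &
                  feats$synonym != "STAR1", ]
  expect_lt(star$p_alt_given_syn, long$p_alt_given_syn)
  expect_equal(star$n_chars, 4L)
  # only synonym of its symbol -> contribution 1
  solo_dict <- build_gene_dictionary(tibble::tibble(symbol = "ONLYSYM",
                                                    synonym = "ONLYSYM"))
  solo_corpus <- toy_corpus(list(pub_id = "s1", year = 2000L,
                                 title = "ONLYSYM does things"))
  solo <- compute_safety_features(solo_dict, solo_corpus,
                                  find_candidates(solo_corpus, solo_dict))
  expect_equal(solo$contribution, 1)
})

test_that("the unsafe rules are disjunctive and classifier independent", {
  lx <- gen_lexicon(seed = 2, n_genes = 40, ambiguity_rate = 0.4)
  corpus <- gen_lexicon_corpus(lx, seed = 3)
  m <- find_candidates(corpus, lx$dictionary)
  feats <- compute_safety_features(lx$dictionary, corpus, m)
  cls <- classify_unsafe(lx$dictionary, feats, n_rounds = 2, n_bags = 8,
                         seed = 4)
  # rules (i), (ii), (iv) hold regardless of the score
  rule_based <- cls$is_english | cls$is_short | cls$is_promiscuous
  expect_true(all(cls$safety[rule_based] == "unsafe"))
  # monotone in the threshold: lowering it never converts unsafe -> safe
  lo <- classify_unsafe(lx$dictionary, feats, threshold = 0.2, n_rounds = 2,
                        n_bags = 8, seed = 4)
  hi <- classify_unsafe(lx$dictionary, feats, threshold = 0.8, n_rounds = 2,
                        n_bags = 8, seed = 4)
  expect_true(all(which(hi$safety == "unsafe") %in% which(lo$safety == "unsafe")))
})

test_that("an English-word synonym like STAR is unsafe by rule (i)", {
  dict <- build_gene_dictionary(tibble::tibble(
    symbol = c("STAR1", "STAR1", "OTHER9"),
    synonym = c("STAR", "Steroidogenic Acute Regulatory Protein", "xq")))
  feats <- tibble::tibble(symbol = dict$symbol, synonym = dict$synonym,
                          total = 1, contribution = 1, n_chars = nchar(dict$synonym),
                          bits = 10, n_nested = 0, p_syn_given_alt = 0.5,
                          p_alt_given_syn = 0.5, is_symbol = FALSE)
  cls <- suppressWarnings(classify_unsafe(dict, feats, n_rounds = 1, n_bags = 2))
  expect_equal(cls$safety[cls$synonym == "STAR"], "unsafe")    # rule (i)
  expect_equal(cls$safety[cls$synonym == "xq"], "unsafe")      # rule (ii)
  expect_equal(cls$safety[grepl("Steroidogenic", cls$synonym)], "safe")
})
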