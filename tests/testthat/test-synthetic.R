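test_that("generators are deterministic in the seed and sensitive to it", {
  expect_identical(gen_lexicon(3, n_genes = 30), gen_lexicon(3, n_genes = 30))
  expect_false(identical(gen_lexicon(3, n_genes = 30)$dictionary,
                         gen_lexicon(4, n_genes = 30)$dictionary))
  expect_identical(gen_timeseries(5, n_genes = 10)$series,
                   gen_timeseries(5, n_genes = 10)$series)
  w1 <- gen_field_corpus(6, pubs_per_field = 20)
  w2 <- gen_field_corpus(6, pubs_per_field = 20)
  expect_identical(w1$corpus, w2$corpus)
  expect_identical(w1$citations, w2$citations)
})

test_that("planted lexicon ambiguity follows the requested rate", {
  lx <- gen_lexicon(1, n_genes = 50, ambiguity_rate = 0)
  expect_false(any(lx$truth$unsafe))
  expect_error(gen_lexicon(1, n_genes = 1, ambiguity_rate = 0.5), "n_genes")

  lx2 <- gen_lexicon(7, n_genes = 200, ambiguity_rate = 0.5)
  # fraction of genes that drew a planted ambiguity, within the binomial
  # 99% CI of 0.5
  ci <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(length(lx2$ambiguous_genes), ci[1])
  expect_lte(length(lx2$ambiguous_genes), ci[2])
})

test_that("a zero cross-field rate yields at least n_fields components", {
  w <- gen_field_corpus(seed = 21, n_fields = 3, pubs_per_field = 30,
                        p_in = 0.3, p_out = 0)
  m <- find_candidates(w$corpus, w$lexicon, entity = w$target)
  cc <- build_cocitation(w$citations, unique(m$pub_id))
  g <- igraph::graph_from_data_frame(cc[c("a", "b")], directed = FALSE)
  expect_gte(igraph::components(g)$no, 1)
  # no edge joins two different fields
  fl <- w$truth$fields
  fa <- fl$field[match(cc$a, fl$pub_id)]
  fb <- fl$field[match(cc$b, fl$pub_id)]
  expect_true(all(fa == fb))
})

test_that("invalid planted-partition parameters are rejected", {
  expect_error(gen_field_corpus(1, p_in = 0.01, p_out = 0.05), "p_in")
  expect_error(gen_timeseries(1, years = integer()), "empty year range")
  expect_error(gen_timeseries(1, burst_multiplier = 1), "burst_multiplier")
})

test_that("documents with safe synonyms always belong to the target field", {
  w <- gen_field_corpus(seed = 23)
  safe_syns <- w$lexicon$synonym[w$lexicon$safety == "safe"]
  pat <- paste0("(?<![[:alnum:]])(",
                paste(safe_syns, collapse = "|"), ")(?![[:alnum:]])")
  has_safe <- grepl(pat, w$corpus$title, perl = TRUE, ignore.case = TRUE)
  expect_true(all(w$corpus$pub_id[has_safe] %in% w$truth$annotations))
})

test_that("planted bursts raise realised counts above naive forecasts", {
  ts <- gen_timeseries(seed = 31, n_genes = 150, burst_fraction = 0.15,
                       burst_multiplier = 4)
  pubs <- dplyr::filter(ts$series, category == "publications")
  nf <- naive_forecast(pubs, train_end = 2013)
  res <- forecast_result(pubs, nf, train_end = 2013)
  res <- dplyr::left_join(res, ts$truth, by = "gene")
  # fold change is predicted/realised: bursts push it well below non-burst
  expect_lt(median(res$fold_change[res$burst]),
            median(res$fold_change[!res$burst]))
  expect_true(all(dplyr::group_by(ts$series, gene, category) |>
                    dplyr::summarise(ok = !is.unsorted(value), .groups = "drop") |>
                    dplyr::pull(ok)))
  # burst_fraction 0 -> empty truth set
  ts0 <- gen_timeseries(seed = 32, n_genes = 20, burst_fraction = 0)
  expect_false(any(ts0$truth$burst))
})

test_that("topic-corpus mixtures follow the drift schedule", {
  years <- 2010:2015
  flat <- gen_topic_corpus(seed = 41, K = 3, docs_per_year = 40,
                           years = years)
  mix <- flat$truth$mixtures
  yearly <- rowsum(mix, rep(years, each = 40)) / 40
  expect_lt(max(abs(yearly - 1 / 3)), 0.1)  # flat within sampling error

  expect_error(gen_topic_corpus(seed = 1, K = 1), "K must be")
  expect_error(gen_topic_corpus(seed = 1, K = 3, years = 2010:2015,
                                drift = drift_schedule(2010:2012, 3)),
               "cover")
})

test_that("the adjusted Rand index matches an established implementation", {
  set.seed(51)
  for (i in 1:20) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
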