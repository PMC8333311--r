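test_that("pagerank matches the dense oracle on random graphs", {
  set.seed(81)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    ids <- sprintf("n%02d", seq_len(n))
    m <- sample(n:(3 * n), 1)
    ed <- tibble::tibble(citing = sample(ids, m, replace = TRUE),
                         cited = sample(ids, m, replace = TRUE)) |>
      dplyr::filter(citing != cited) |> dplyr::distinct()
    got <- pagerank(ed, nodes = ids)
    want <- oracle_pagerank(ed, ids)
    expect_lt(max(abs(got$score - want$score)), 1e-8)
  }
})

test_that("pagerank limit cases are exact", {
  expect_equal(pagerank(tibble::tibble(citing = character(),
                                       cited = character()),
                        nodes = "only")$score, 1)
  two <- pagerank(tibble::tibble(citing = c("a", "b"), cited = c("b", "a")))
  expect_equal(two$score, c(0.5, 0.5))
})

test_that("review scores are PageRank-normalised coverage", {
  pubs <- sprintf("p%02d", 1:10)
  ed <- tibble::tibble(
    citing = c(rep("rAll", 10), rep("rHalf", 5), "rOther"),
    cited = c(pubs, pubs[1:5], "somewhere"))
  cov <- review_coverage(ed, pubs, reviews = c("rAll", "rHalf", "rNone"))
  pr <- tibble::tibble(pub_id = pubs, score = rep(0.1, 10))
  sc <- score_reviews(cov, pr)
  expect_equal(sc$score[sc$review_id == "rAll"], 1)
  expect_equal(sc$score[sc$review_id == "rHalf"], 0.5)
  expect_equal(sc$score[sc$review_id == "rNone"], 0)
})

test_that("union mode separates disjoint pairs from identical pairs", {
  pubs <- sprintf("p%02d", 1:10)
  cov <- Matrix::sparseMatrix(
    i = c(1:5, 6:10, 1:5, 1:5),
    j = c(rep(1, 5), rep(2, 5), rep(3, 5), rep(4, 5)), x = 1,
    dims = c(10, 4), dimnames = list(pubs, c("rA", "rB", "rA2", "rA3")))
  pr <- tibble::tibble(pub_id = pubs, score = rep(0.1, 10))
  ru <- recommend(cov, pr, r_min = 2, r_max = 2, mode = "union")
  top <- ru[1, ]
  expect_setequal(top$reviews[[1]], c("rA", "rB"))
  expect_equal(top$score, 1)
  dup_score <- ru$score[vapply(ru$reviews, function(r) {
    setequal(r, c("rA2", "rA3")) }, logical(1))]
  expect_equal(dup_score, 0.5)
  rl <- recommend(cov, pr, r_min = 2, r_max = 2, mode = "literal")
  lit <- function(set) rl$score[vapply(rl$reviews, setequal, logical(1), set)]
  expect_equal(lit(c("rA", "rB")), lit(c("rA2", "rA3")))  # literal ties them
})

test_that("exhaustive ranking equals brute force on the 6x12 fixture", {
  set.seed(82)
  pubs <- sprintf("p%02d", 1:12)
  revs <- sprintf("r%d", 1:6)
  cov <- Matrix::Matrix(matrix(rbinom(72, 1, 0.35), 12, 6,
                               dimnames = list(pubs, revs)), sparse = TRUE)
  pr <- tibble::tibble(pub_id = pubs,
                       score = {
                         s <- runif(12); s / sum(s)
                       })
  for (mode in c("union", "literal")) {
    rec <- recommend(cov, pr, r_min = 2, r_max = 2, mode = mode)
    # brute force over all 15 pairs
    prs <- utils::combn(6, 2)
    brute <- vapply(seq_len(ncol(prs)), function(j) {
      rs <- Matrix::rowSums(cov[, prs[, j], drop = FALSE])
      if (mode == "union") rs <- as.numeric(rs > 0)
      sum(rs * pr$score) / sum(pr$score)
    }, numeric(1))
    ord <- order(-brute)
    expect_equal(rec$score, brute[ord], tolerance = 1e-12)
    for (k in seq_len(nrow(rec))) {
      expect_setequal(rec$reviews[[k]], revs[prs[, ord[k]]])
    }
  }
})

test_that("greedy fallback achieves the (1 - 1/e) coverage bound", {
  set.seed(83)
  for (rep in 1:20) {
    n_pub <- 15; n_rev <- 8
    pubs <- sprintf("p%02d", seq_len(n_pub))
    cov <- Matrix::Matrix(matrix(rbinom(n_pub * n_rev, 1, 0.3), n_pub, n_rev,
                                 dimnames = list(pubs, sprintf("r%d", 1:n_rev))),
                          sparse = TRUE)
    pr <- tibble::tibble(pub_id = pubs, score = { s <- runif(n_pub); s / sum(s) })
    exact <- recommend(cov, pr, r_min = 3, r_max = 3, mode = "union")
    greedy <- suppressMessages(
      recommend(cov, pr, r_min = 3, r_max = 3, mode = "union",
                max_combinations = 1))
    expect_gte(greedy$score[1], (1 - 1 / exp(1)) * max(exact$score) - 1e-12)
  }
})

test_that("combinations carry mean cited year and topic profiles", {
  pubs <- c("p1", "p2", "p3")
  cov <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 2), x = 1,
                              dims = c(3, 2),
                              dimnames = list(pubs, c("rA", "rB")))
  pr <- tibble::tibble(pub_id = pubs, score = rep(1 / 3, 3))
  dates <- tibble::tibble(pub_id = pubs, year = c(2000, 2010, 2020))
  v <- fit_vectorizer(list(c("aaa", "bbb"), c("aaa", "ccc"), c("bbb", "ccc")),
                      min_count = 1, max_df = 2, doc_ids = pubs)
  tm <- fit_topics(v, K = 2, seed = 1)
  rec <- recommend(cov, pr, r_min = 1, r_max = 1, dates = dates, topics = tm)
  rA <- rec[vapply(rec$reviews, identical, logical(1), "rA"), ]
  expect_equal(rA$mean_year, 2005)
  expect_equal(length(rA$topic_profile[[1]]), 2)
  expect_error(recommend(cov, pr, r_min = 0, r_max = 1), "r_min")
})
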