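test_that("co-citation construction matches the brute-force triple oracle", {
  set.seed(41)
  for (rep in 1:50) {
    n <- 50
    ids <- sprintf("n%02d", 1:n)
    m <- sample(30:120, 1)
    ed <- tibble::tibble(citing = sample(ids, m, replace = TRUE),
                         cited = sample(ids, m, replace = TRUE)) |>
      dplyr::filter(citing != cited) |>
      dplyr::distinct()
    cand <- sample(ids, sample(10:40, 1))
    got <- build_cocitation(ed, cand) |>
      dplyr::arrange(a, b) |>
      tibble::as_tibble()
    want <- oracle_cocitation(ed, cand)
    expect_equal(got$a, want$a)
    expect_equal(got$b, want$b)
    expect_equal(as.integer(got$weight), want$weight)
  }
})

test_that("simple co-citation cases follow the definition", {
  expect_equal(nrow(build_cocitation(
    tibble::tibble(citing = "C", cited = "A"), c("A", "B"))), 0)
  g <- build_cocitation(
    tibble::tibble(citing = c("C", "C", "D", "D"),
                   cited = c("A", "B", "A", "B")), c("A", "B"))
  expect_equal(g$weight, 2)
})

test_that("fast-greedy community detection splits canonical structures", {
  # two triangles joined by a single weight-1 edge
  tri <- function(x, y, z) tibble::tibble(a = c(x, y, x), b = c(y, z, z),
                                          weight = 1)
  g <- dplyr::bind_rows(tri("a1", "a2", "a3"), tri("b1", "b2", "b3"),
                        tibble::tibble(a = "a3", b = "b1", weight = 1))
  g <- structure(g, nodes = c(paste0("a", 1:3), paste0("b", 1:3)),
                 class = c("genelit_cocitation", class(g)))
  part <- detect_communities(g)
  expect_equal(length(unique(part$community)), 2)
  expect_equal(length(unique(part$community[startsWith(part$pub_id, "a")])), 1)

  single <- structure(tibble::tibble(a = "x", b = "y", weight = 1),
                      nodes = c("x", "y"),
                      class = c("genelit_cocitation", class(g)))
  ps <- detect_communities(single)
  expect_equal(length(unique(ps$community)), 1)
  expect_equal(nrow(ps), 2)
})

test_that("community sizes partition the connected candidate nodes", {
  w <- gen_field_corpus(seed = 9)
  m <- find_candidates(w$corpus, w$lexicon, entity = w$target)
  cand <- unique(m$pub_id)
  cc <- build_cocitation(w$citations, cand)
  conn <- unique(c(cc$a, cc$b))
  part <- detect_communities(structure(cc, nodes = conn, class = class(cc)))
  expect_setequal(part$pub_id, conn)
  expect_equal(sum(table(part$community)), length(conn))
})

test_that("the 0.1% labelling rule and its boundary branches hold", {
  mk_mentions <- function(safe_ids, unsafe_ids) {
    structure(tibble::tibble(
      entity = "G", pub_id = c(safe_ids, unsafe_ids),
      synonym = c(rep("safeSyn", length(safe_ids)),
                  rep("badSyn", length(unsafe_ids))),
      start = 1L, end = 5L,
      safety = c(rep("safe", length(safe_ids)),
                 rep("unsafe", length(unsafe_ids)))),
      class = c("genelit_mentions", "tbl_df", "tbl", "data.frame"))
  }
  # community of 1000: 1 safe + 999 unsafe-only -> ratio 1/999 > 0.001
  ids <- sprintf("p%04d", 1:1000)
  part <- tibble::tibble(pub_id = ids, community = 1L)
  lab <- label_communities(part, mk_mentions(ids[1], ids[-1]))
  expect_true(all(lab$label == "linked"))
  # 1 safe + 1500 unsafe-only -> ratio < 0.001 -> rejected
  ids2 <- sprintf("q%04d", 1:1501)
  part2 <- tibble::tibble(pub_id = ids2, community = 1L)
  lab2 <- label_communities(part2, mk_mentions(ids2[1], ids2[-1]))
  expect_true(all(lab2$label == "rejected"))
  # all-safe community -> linked; zero-safe -> rejected
  part3 <- tibble::tibble(pub_id = c("s1", "s2", "u1"),
                          community = c(1L, 1L, 2L))
  lab3 <- label_communities(part3, mk_mentions(c("s1", "s2"), "u1"))
  expect_equal(lab3$label[lab3$community == 1], rep("linked", 2))
  expect_equal(lab3$label[lab3$community == 2], "rejected")
})

test_that("disconnected safe-mention documents are linked without a classifier", {
  w <- gen_field_corpus(seed = 12)
  ann <- disambiguate(w$corpus, w$citations, w$lexicon, w$target, seed = 1)
  safe_direct <- ann$pub_id[ann$provenance == "safe-direct"]
  m <- find_candidates(w$corpus, w$lexicon, entity = w$target)
  counts <- safe_mention_counts(m)
  expect_true(all(safe_direct %in% counts$pub_id[counts$n_safe > 0]))
  expect_true(all(safe_direct %in% w$truth$disconnected))
})

test_that("zero candidates and zero disconnected documents are handled", {
  w <- gen_field_corpus(seed = 13, disconnected_fraction = 0)
  dict2 <- dplyr::bind_rows(
    w$lexicon,
    tibble::tibble(symbol = "GHOST1", synonym = "phantomin gene",
                   is_nested = FALSE, is_promiscuous = FALSE,
                   is_english = FALSE, is_short = FALSE, safety = "safe"))
  empty_ann <- disambiguate(w$corpus, w$citations, dict2, "GHOST1")
  expect_equal(nrow(empty_ann), 0)
  expect_equal(nrow(classify_disconnected(w$corpus, "a", "b", character(),
                                          find_candidates(w$corpus, w$lexicon,
                                                          entity = w$target))),
               0)
})

test_that("annotation adds a document when it gains a safe mention", {
  w <- gen_field_corpus(seed = 14)
  ann0 <- disambiguate(w$corpus, w$citations, w$lexicon, w$target, seed = 2)
  # take a field-2 candidate (ambiguous-only) NOT annotated, add a safe
  # synonym to its title: it must now be annotated (monotonicity)
  m <- find_candidates(w$corpus, w$lexicon, entity = w$target)
  f2 <- w$truth$fields$pub_id[w$truth$fields$field == 2]
  victim <- setdiff(intersect(f2, unique(m$pub_id)), ann0$pub_id)[1]
  expect_false(is.na(victim))  # the planted world always rejects field-2 docs
  corpus2 <- w$corpus
  i <- match(victim, corpus2$pub_id)
  corpus2$title[i] <- paste(corpus2$title[i], "targetin alpha receptor")
  ann1 <- suppressWarnings(
    disambiguate(corpus2, w$citations, w$lexicon, w$target, seed = 2))
  expect_true(victim %in% ann1$pub_id)
})

test_that("evaluation against a reference computes macro recall and precision", {
  ann <- structure(tibble::tibble(
    entity = c("g1", "g1", "g2", "g3"),
    pub_id = c("a", "b", "c", "x"), provenance = "community"),
    class = c("genelit_annotations", "tbl_df", "tbl", "data.frame"))
  ref <- tibble::tibble(entity = c("g1", "g1", "g2", "g2", "g3"),
                        pub_id = c("a", "z", "c", "d", "y"))
  ev <- evaluate_against_reference(ann, ref)
  by <- tidy(ev)
  expect_equal(by$recall[by$entity == "g1"], 0.5)
  expect_equal(by$precision[by$entity == "g1"], 0.5)
  expect_equal(by$recall[by$entity == "g2"], 0.5)
  expect_equal(by$precision[by$entity == "g2"], 1)
  expect_equal(by$recall[by$entity == "g3"], 0)
  expect_equal(glance(ev)$recall, mean(c(0.5, 0.5, 0)))
  expect_equal(glance(ev)$precision, mean(c(0.5, 1, 0)))
  # identity and disjoint extremes
  same <- evaluate_against_reference(ann, tibble::tibble(
    entity = ann$entity, pub_id = ann$pub_id))
  expect_equal(glance(same)$recall, 1)
  expect_equal(glance(same)$precision, 1)
  expect_error(evaluate_against_reference(ann, ref[0, ]), "empty")
})
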