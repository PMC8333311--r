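#' Generate a synthetic gene lexicon with planted ambiguity
#'
#' Every gene gets a unique synthetic symbol plus one unique long synonym.
#' With probability `ambiguity_rate` a gene additionally receives one planted
#' ambiguous synonym of a random kind: an English word (drawn from the bundled
#' word list), a two-character token, a promiscuous token (also attached to a
#' second gene), or a nested token (a word-bounded substring of a longer
#' synonym planted on another gene). Planted ambiguous synonyms are unsafe in
#' the ground truth; everything else is safe.
#'
#' @param seed Integer seed; output is a pure function of (seed, parameters).
#' @param n_genes Number of genes (at least 2 when any ambiguity is
#'   requested, since promiscuity needs a second gene).
#' @param ambiguity_rate Probability that a gene gets a planted ambiguous
#'   synonym.
#' @param nested_safe_rate Probability that a gene's long synonym gets a safe
#'   nested sibling (a longer variant containing it); real dictionaries are
#'   full of nested-but-safe synonym pairs, so nestedness alone must not
#'   predict safety.
#' @return A list with `dictionary` (from [build_gene_dictionary()], classes
#'   computed, safety `"unknown"`), `truth` (tibble `symbol`, `synonym`,
#'   `unsafe`, `type`) and `ambiguous_genes` (the symbols that drew a
#'   planted ambiguity).
#' @export
gen_lexicon <- function(seed, n_genes = 200L, ambiguity_rate = 0.3,
                        nested_safe_rate = 0.25) {
  stopifnot(ambiguity_rate >= 0, ambiguity_rate <= 1)
  if (n_genes < 2 && ambiguity_rate > 0) {
    abort("n_genes must be >= 2 when ambiguity is requested (promiscuity needs two genes)")
  }
  set.seed(seed)
  symbols <- sprintf("GSY%04dQ", seq_len(n_genes))
  long_syn <- sprintf("synthetic factor %04d homolog", seq_len(n_genes))
  rows <- tibble(symbol = rep(symbols, 2), synonym = c(symbols, long_syn))
  truth <- tibble(symbol = rows$symbol, synonym = rows$synonym,
                  unsafe = FALSE, type = "safe")

  ambiguous <- runif(n_genes) < ambiguity_rate
  eng_pool <- sample(genelit_english_words())
  eng_i <- 0L; prm_i <- 0L; nst_i <- 0L
  shorts <- character()
  for (g in which(ambiguous)) {
    type <- sample(c("english", "short", "promiscuous", "nested"), 1)
    if (type == "english") {
      eng_i <- eng_i + 1L
      tok <- eng_pool[eng_i]
      rows <- bind_rows(rows, tibble(symbol = symbols[g], synonym = tok))
      truth <- bind_rows(truth, tibble(symbol = symbols[g], synonym = tok,
                                       unsafe = TRUE, type = "english"))
    } else if (type == "short") {
      repeat {
        tok <- paste0(sample(letters, 1), sample(c(letters, 0:9), 1))
        if (!tok %in% shorts) break
      }
      shorts <- c(shorts, tok)
      rows <- bind_rows(rows, tibble(symbol = symbols[g], synonym = tok))
      truth <- bind_rows(truth, tibble(symbol = symbols[g], synonym = tok,
                                       unsafe = TRUE, type = "short"))
    } else if (type == "promiscuous") {
      prm_i <- prm_i + 1L
      tok <- sprintf("PRS%04dQ", prm_i)  # former-symbol style, like real promiscuous names
      other <- sample(setdiff(seq_len(n_genes), g), 1)
      rows <- bind_rows(rows, tibble(symbol = symbols[c(g, other)], synonym = tok))
      truth <- bind_rows(truth, tibble(symbol = symbols[c(g, other)],
                                       synonym = tok, unsafe = TRUE,
                                       type = "promiscuous"))
    } else {
      nst_i <- nst_i + 1L
      tok <- sprintf("NSD%04dQ", nst_i)  # symbol-style, nested inside a longer name
      host <- paste(tok, "binding element")
      other <- sample(setdiff(seq_len(n_genes), g), 1)
      rows <- bind_rows(rows,
                        tibble(symbol = c(symbols[g], symbols[other]),
                               synonym = c(tok, host)))
      truth <- bind_rows(truth,
                         tibble(symbol = c(symbols[g], symbols[other]),
                                synonym = c(tok, host),
                                unsafe = c(TRUE, FALSE),
                                type = c("nested", "safe")))
    }
  }
  sibling <- runif(n_genes) < nested_safe_rate
  if (any(sibling)) {
    sib_syn <- paste(long_syn[sibling], "isoform beta")
    rows <- bind_rows(rows, tibble(symbol = symbols[sibling], synonym = sib_syn))
    truth <- bind_rows(truth, tibble(symbol = symbols[sibling],
                                     synonym = sib_syn,
                                     unsafe = FALSE, type = "safe"))
  }
  dict <- build_gene_dictionary(rows)
  truth <- distinct(truth, .data$symbol, .data$synonym, .keep_all = TRUE)
  list(dictionary = dict, truth = arrange(truth, .data$symbol, .data$synonym),
       ambiguous_genes = symbols[ambiguous])
}

#' Generate a corpus exercising a planted lexicon
#'
#' Builds documents in which each gene's own synonyms co-occur (giving high
#' conditional mention probabilities for safe synonyms) while planted
#' ambiguous tokens additionally appear in background documents with no gene
#' context (high candidate totals, low conditional probabilities) - the usage
#' signature the safety features are designed to pick up.
#'
#' @param lexicon Output of [gen_lexicon()].
#' @param seed Integer seed.
#' @param docs_per_gene Documents written about each gene.
#' @param background_per_ambiguous Background documents per planted ambiguous
#'   synonym.
#' @return A corpus tibble.
#' @export
gen_lexicon_corpus <- function(lexicon, seed, docs_per_gene = 4L,
                               background_per_ambiguous = 10L) {
  set.seed(seed)
  dict <- lexicon$dictionary
  truth <- lexicon$truth
  filler <- sprintf("filw%03dz", 1:150)
  mk_doc <- function(id, mention_syns) {
    words <- sample(filler, 14, replace = TRUE)
    tibble(pub_id = id,
           title = paste(c(words[1:4], mention_syns), collapse = " "),
           abstract = paste(words[5:14], collapse = " "),
           keywords = list(character()), year = sample(2000:2019, 1),
           is_review = FALSE, is_trial = FALSE,
           affiliations = list(character()), pharma_class = "none")
  }
  docs <- list(); k <- 0L
  for (sym in unique(dict$symbol)) {
    syns <- dict$synonym[dict$symbol == sym]
    long <- syns[grepl("^synthetic factor", syns)][1]
    others <- setdiff(syns, long)
    for (d in seq_len(docs_per_gene)) {
      mention <- c(long, others[runif(length(others)) < 0.45])
      k <- k + 1L
      docs[[k]] <- mk_doc(sprintf("L%05d", k), mention)
    }
  }
  amb <- truth$synonym[truth$unsafe]
  for (tok in unique(amb)) {
    for (d in seq_len(background_per_ambiguous)) {
      k <- k + 1L
      docs[[k]] <- mk_doc(sprintf("L%05d", k), tok)
    }
  }
  validate_corpus(list_rbind(docs))
}

#' Generate a field-structured corpus with planted communities
#'
#' Emulates the disambiguation setting: several research fields share one
#' ambiguous token while only the target field truly refers to the gene. The
#' planted citation structure yields a co-citation graph whose edge
#' probability is `p_in` within fields and `p_out` across fields
#' (planted-partition construction), with a fraction of candidate documents
#' left disconnected from the citation graph.
#'
#' @param seed Integer seed.
#' @param n_fields Number of fields; field 1 is the target gene's field.
#' @param pubs_per_field Documents per field.
#' @param p_in,p_out Within/across-field co-citation pair probabilities;
#'   requires `p_in > p_out`.
#' @param lexicon Optional synonym dictionary with safety labels; defaults to
#'   a pocket lexicon with one target gene (`TGT1`: safe synonyms `"TGT1"`
#'   and `"targetin alpha receptor"`, unsafe English-word synonym `"orca"`).
#' @param safe_rate Probability a target-field document carries a safe
#'   synonym.
#' @param ambig_target_rate Probability a target-field document carries the
#'   ambiguous synonym.
#' @param ambig_other_rate Probability a non-target-field document carries the
#'   ambiguous token (in its other meaning).
#' @param disconnected_fraction Fraction of candidate documents per field kept
#'   out of the citation graph.
#' @return A list of class `genelit_world`: `corpus`, `citations`, `lexicon`,
#'   `target` (the gene symbol) and `truth` (list with `annotations` - the
#'   pub_ids truly about the gene - and `fields` - tibble `pub_id`, `field`
#'   for candidate documents).
#' @export
gen_field_corpus <- function(seed, n_fields = 3L, pubs_per_field = 60L,
                             p_in = 0.2, p_out = 0.005, lexicon = NULL,
                             safe_rate = 0.6, ambig_target_rate = 0.5,
                             ambig_other_rate = 0.7,
                             disconnected_fraction = 0.25) {
  if (p_in <= p_out) abort("p_in must exceed p_out (communities unrecoverable)")
  set.seed(seed)
  if (is.null(lexicon)) {
    lexicon <- tibble(
      symbol = "TGT1",
      synonym = c("TGT1", "targetin alpha receptor", "orca"),
      is_nested = FALSE, is_promiscuous = FALSE,
      is_english = c(FALSE, FALSE, TRUE), is_short = FALSE,
      safety = c("safe", "safe", "unsafe")
    )
  }
  target <- lexicon$symbol[1]
  safe_syns <- lexicon$synonym[lexicon$symbol == target & lexicon$safety == "safe"]
  amb <- lexicon$synonym[lexicon$symbol == target & lexicon$safety == "unsafe"][1]
  if (is.na(amb)) abort("lexicon must contain an unsafe synonym for the target")

  vocab <- lapply(seq_len(n_fields), function(f) sprintf("fld%dw%02dz", f, 1:30))
  docs <- list(); fields <- integer(); k <- 0L
  truth_ann <- character()
  for (f in seq_len(n_fields)) {
    for (d in seq_len(pubs_per_field)) {
      k <- k + 1L
      id <- sprintf("P%04d", k)
      mention <- character()
      if (f == 1) {
        if (runif(1) < safe_rate) mention <- sample(safe_syns, 1)
        if (runif(1) < ambig_target_rate) mention <- c(mention, amb)
        if (length(mention) == 0) mention <- sample(safe_syns, 1)
        truth_ann <- c(truth_ann, id)
      } else if (runif(1) < ambig_other_rate) {
        mention <- amb
      }
      words <- sample(vocab[[f]], 24, replace = TRUE)
      docs[[k]] <- tibble(
        pub_id = id,
        title = paste(c(words[1:4], mention), collapse = " "),
        abstract = paste(words[5:24], collapse = " "),
        keywords = list(character()), year = sample(2000:2019, 1),
        is_review = FALSE, is_trial = FALSE,
        affiliations = list(character()), pharma_class = "none")
      fields[k] <- f
    }
  }
  corpus <- list_rbind(docs)
  syn_pat <- paste0("(?<![[:alnum:]])(",
                    paste(escape_regex(c(safe_syns, amb)), collapse = "|"),
                    ")(?![[:alnum:]])")
  is_cand <- str_detect(corpus$title, regex(syn_pat, ignore_case = TRUE))
  cand_ids <- corpus$pub_id[is_cand]
  cand_fields <- fields[is_cand]

  # disconnected candidates, stratified by field
  disconnected <- unlist(lapply(unique(cand_fields), function(f) {
    ids <- cand_ids[cand_fields == f]
    sample(ids, size = floor(disconnected_fraction * length(ids)))
  }))
  connected <- setdiff(cand_ids, disconnected)
  conn_field <- cand_fields[match(connected, cand_ids)]

  # planted-partition co-citations: one citing document per sampled pair
  pairs <- utils::combn(seq_along(connected), 2)
  same <- conn_field[pairs[1, ]] == conn_field[pairs[2, ]]
  prob <- ifelse(same, p_in, p_out)
  take <- runif(ncol(pairs)) < prob
  cit_rows <- list(); cdocs <- list()
  idx <- which(take)
  for (j in seq_along(idx)) {
    cid <- sprintf("C%05d", j)
    cdocs[[j]] <- tibble(
      pub_id = cid, title = "citing survey piece",
      abstract = paste(sample(sprintf("citw%02dz", 1:20), 8, replace = TRUE),
                       collapse = " "),
      keywords = list(character()), year = sample(2000:2019, 1),
      is_review = FALSE, is_trial = FALSE, affiliations = list(character()),
      pharma_class = "none")
    cit_rows[[j]] <- tibble(citing = cid,
                            cited = connected[pairs[, idx[j]]])
  }
  corpus <- validate_corpus(bind_rows(corpus, list_rbind(cdocs)))
  citations <- if (length(cit_rows)) list_rbind(cit_rows) else {
    tibble(citing = character(), cited = character())
  }
  structure(list(
    corpus = corpus, citations = citations, lexicon = lexicon,
    target = target,
    truth = list(annotations = truth_ann,
                 fields = tibble(pub_id = cand_ids, field = cand_fields),
                 disconnected = disconnected)
  ), class = "genelit_world")
}

#' Generate per-gene yearly count series with planted bursts
#'
#' Baseline yearly new-publication counts are Poisson draws around a smooth
#' exponential growth curve per gene; citations are proportional to
#' publications, and the review/trial/pharma categories are binomial
#' thinnings. A `burst_fraction` of genes has new counts multiplied by
#' `burst_multiplier` from a planted year inside the forecast window onward.
#' Series are returned cumulatively for all ten categories.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param years Year range (calendar years, ascending).
#' @param burst_fraction Fraction of genes with a planted burst.
#' @param burst_multiplier Multiplier (> 1) applied to new counts from the
#'   burst year on.
#' @param train_end Last training year; planted burst years fall after it.
#' @return A list: `series` (long tibble `gene`, `category`, `year`, `value`
#'   with cumulative counts) and `truth` (tibble `gene`, `burst`,
#'   `burst_year`).
#' @export
gen_timeseries <- function(seed, n_genes = 200L, years = 1980:2019,
                           burst_fraction = 0.1, burst_multiplier = 4,
                           train_end = 2013L) {
  if (length(years) == 0) abort("empty year range")
  if (burst_multiplier <= 1) abort("burst_multiplier must exceed 1")
  set.seed(seed)
  post <- years[years > train_end]
  burst_years_pool <- if (length(post) > 2) post[seq_len(length(post) - 2)] else post
  genes <- sprintf("G%04d", seq_len(n_genes))
  burst <- runif(n_genes) < burst_fraction
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    a <- runif(1, 0.5, 3); r <- runif(1, 0.02, 0.09)
    lambda <- a * exp(r * (years - years[1]))
    new_pub <- rpois(length(years), lambda)
    byear <- NA_integer_
    if (burst[i] && length(burst_years_pool)) {
      byear <- sample(burst_years_pool, 1)
      sel <- years >= byear
      new_pub[sel] <- new_pub[sel] * burst_multiplier
    }
    cit_rate <- runif(1, 3, 10)
    new_cit <- rpois(length(years), cit_rate * new_pub)
    thin <- function(n, p) rbinom(length(n), n, p)
    cats <- list(
      publications = new_pub,
      reviews = thin(new_pub, 0.2),
      trials = thin(new_pub, 0.05),
      pub_big_pharma = thin(new_pub, 0.08),
      pub_med_pharma = thin(new_pub, 0.08),
      citations = new_cit,
      cit_reviews = thin(new_cit, 0.2),
      cit_trials = thin(new_cit, 0.05),
      cit_big_pharma = thin(new_cit, 0.08),
      cit_med_pharma = thin(new_cit, 0.08)
    )
    rows[[i]] <- list_rbind(imap(cats, function(v, nm) {
      tibble(gene = genes[i], category = nm, year = years,
             value = cumsum(v))
    }))
    attr(rows[[i]], "byear") <- byear
  }
  truth <- tibble(gene = genes, burst = burst,
                  burst_year = vapply(rows, function(r) attr(r, "byear"),
                                      integer(1)))
  list(series = list_rbind(rows), truth = truth)
}

#' Generate a topic-mixture corpus with a drift schedule
#'
#' Each document's expected topic mixture follows the year-indexed drift
#' schedule; realised mixtures are Dirichlet draws around it and words are
#' sampled from planted topic-term distributions over disjoint per-topic
#' vocabularies.
#'
#' @param seed Integer seed.
#' @param K Number of topics (at least 2).
#' @param docs_per_year Documents generated per calendar year.
#' @param years Calendar years to cover.
#' @param drift A tibble (`year`, `topic`, `weight`) covering all `years`
#'   (weights are normalised per year), or `NULL` for a flat schedule. See
#'   [drift_schedule()].
#' @param words_per_doc Words sampled per document.
#' @param vocab_per_topic Vocabulary size per topic.
#' @param concentration Dirichlet concentration around the scheduled mixture.
#' @return A list: `corpus` (tibble), `truth` (list with `mixtures` (docs x
#'   K), `topic_terms` (K x vocabulary), `vocab`, `drift`).
#' @export
gen_topic_corpus <- function(seed, K = 3L, docs_per_year = 30L,
                             years = 2008:2019, drift = NULL,
                             words_per_doc = 40L, vocab_per_topic = 25L,
                             concentration = 3) {
  if (K < 2) abort("K must be at least 2")
  set.seed(seed)
  if (is.null(drift)) {
    drift <- tidyr::expand_grid(year = years, topic = seq_len(K)) |>
      mutate(weight = 1 / K)
  }
  drift <- as_tibble(drift)
  if (!all(years %in% drift$year)) abort("drift schedule does not cover all document years")

  vocab <- lapply(seq_len(K), function(k) {
    sprintf("top%02dw%02dz", k, seq_len(vocab_per_topic))
  })
  all_words <- unlist(vocab)
  topic_terms <- matrix(0, K, length(all_words),
                        dimnames = list(NULL, all_words))
  for (k in seq_len(K)) {
    w <- rgamma(vocab_per_topic, 2, 1)
    topic_terms[k, vocab[[k]]] <- w / sum(w)
  }

  docs <- list(); mixes <- list(); k_doc <- 0L
  for (y in years) {
    sched <- drift |> filter(.data$year == y) |> arrange(.data$topic) |> pull(.data$weight)
    sched <- pmax(sched, 1e-6); sched <- sched / sum(sched)
    for (d in seq_len(docs_per_year)) {
      k_doc <- k_doc + 1L
      gam <- rgamma(K, shape = concentration * sched, rate = 1)
      mix <- gam / sum(gam)
      word_prob <- as.numeric(mix %*% topic_terms)
      words <- sample(all_words, words_per_doc, replace = TRUE, prob = word_prob)
      docs[[k_doc]] <- tibble(
        pub_id = sprintf("T%05d", k_doc),
        title = paste(words[1:5], collapse = " "),
        abstract = paste(words[-(1:5)], collapse = " "),
        keywords = list(character()), year = y,
        is_review = FALSE, is_trial = FALSE,
        affiliations = list(character()), pharma_class = "none")
      mixes[[k_doc]] <- mix
    }
  }
  list(corpus = validate_corpus(list_rbind(docs)),
       truth = list(mixtures = do.call(rbind, mixes),
                    topic_terms = topic_terms, vocab = vocab, drift = drift))
}

#' A linear-ramp drift schedule
#'
#' Convenience builder for [gen_topic_corpus()]: one topic's expected weight
#' ramps linearly from `from` to `to` across the years while the others share
#' the remainder equally.
#'
#' @param years Calendar years.
#' @param K Number of topics.
#' @param ramp_topic Which topic ramps (default 1).
#' @param from,to Start and end expected weights of the ramping topic.
#' @return A tibble `year`, `topic`, `weight`.
#' @export
drift_schedule <- function(years, K, ramp_topic = 1L, from = 0, to = 0.6) {
  ramp <- seq(from, to, length.out = length(years))
  list_rbind(lapply(seq_along(years), function(i) {
    w <- rep((1 - ramp[i]) / (K - 1), K)
    w[ramp_topic] <- ramp[i]
    tibble(year = years[i], topic = seq_len(K), weight = w)
  }))
}

#' Adjusted Rand index between two labellings
#'
#' @param x,y Two label vectors of equal length.
#' @return The adjusted Rand index (1 for identical partitions, ~0 for
#'   independent ones).
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(x)
  expected <- sum_i * sum_j / comb2(n)
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
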