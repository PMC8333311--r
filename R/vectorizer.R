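#' Fit an n-gram TF-IDF vectoriser
#'
#' Extracts uni- to tetra-grams from preprocessed token streams, keeps n-grams
#' with a total corpus count of at least `min_count` and a document frequency
#' strictly below `max_df`, and weights them by TF-IDF.
#'
#' The pinned TF-IDF convention is the smoothed, add-one form
#' `idf(t) = log((1 + N) / (1 + df(t))) + 1` applied to raw term counts,
#' followed by L2 row normalisation. Transforming unseen documents (see
#' [dtm_transform()]) uses the fitted vocabulary and IDF only.
#'
#' @param docs A list of token streams (character vectors, e.g. from
#'   [preprocess()]), or a character vector of raw texts, which are
#'   preprocessed first.
#' @param ngram_max Largest n-gram order (default 4).
#' @param min_count Minimum total corpus count to retain an n-gram.
#' @param max_df Maximum document frequency (fraction of documents) to retain
#'   an n-gram; the bound is strict.
#' @param doc_ids Optional document identifiers (default `seq_along(docs)`).
#' @return An object of class `genelit_dtm` with elements `tfidf` (sparse
#'   documents x terms matrix), `counts` (raw count matrix), `vocabulary`
#'   (tibble with `term`, `count`, `df`), `idf`, and the fit parameters.
#' @export
fit_vectorizer <- function(docs, ngram_max = 4L, min_count = 2L, max_df = 0.6,
                           doc_ids = NULL) {
  if (is.character(docs)) docs <- lapply(docs, preprocess)
  stopifnot(is.list(docs), length(docs) >= 1)
  doc_ids <- doc_ids %||% as.character(seq_along(docs))
  n_docs <- length(docs)

  grams <- lapply(docs, extract_ngrams, ngram_max = ngram_max)
  tallies <- lapply(grams, function(g) table(g))
  term_all <- unlist(lapply(tallies, names), use.names = FALSE)
  count_all <- unlist(lapply(tallies, as.integer), use.names = FALSE)
  doc_all <- rep(seq_len(n_docs), vapply(tallies, length, integer(1)))

  if (length(term_all) == 0) abort("empty vocabulary")
  totals <- rowsum(count_all, term_all)
  dfreq <- rowsum(rep(1L, length(term_all)), term_all)
  keep <- rownames(totals)[totals[, 1] >= min_count &
                             dfreq[, 1] / n_docs < max_df]
  if (length(keep) == 0) abort("empty vocabulary")
  keep <- sort(keep)

  sel <- term_all %in% keep
  term_idx <- match(term_all[sel], keep)
  counts <- sparseMatrix(i = doc_all[sel], j = term_idx, x = count_all[sel],
                         dims = c(n_docs, length(keep)),
                         dimnames = list(doc_ids, keep))
  df_keep <- dfreq[keep, 1]
  idf <- log((1 + n_docs) / (1 + df_keep)) + 1

  structure(list(
    tfidf = tfidf_weight(counts, idf),
    counts = counts,
    vocabulary = tibble(term = keep, count = as.integer(totals[keep, 1]),
                        df = as.integer(df_keep)),
    idf = idf,
    ngram_max = ngram_max, min_count = min_count, max_df = max_df,
    n_docs = n_docs
  ), class = "genelit_dtm")
}

#' Transform documents with a fitted vectoriser
#'
#' @param vectorizer A `genelit_dtm` from [fit_vectorizer()].
#' @param docs Token streams or raw texts.
#' @param doc_ids Optional document identifiers.
#' @return A sparse TF-IDF matrix over the fitted vocabulary.
#' @export
dtm_transform <- function(vectorizer, docs, doc_ids = NULL) {
  stopifnot(inherits(vectorizer, "genelit_dtm"))
  if (is.character(docs)) docs <- lapply(docs, preprocess)
  doc_ids <- doc_ids %||% as.character(seq_along(docs))
  vocab <- vectorizer$vocabulary$term
  grams <- lapply(docs, extract_ngrams, ngram_max = vectorizer$ngram_max)
  trip <- lapply(seq_along(grams), function(i) {
    tab <- table(grams[[i]])
    j <- match(names(tab), vocab)
    ok <- !is.na(j)
    list(i = rep(i, sum(ok)), j = j[ok], x = as.numeric(tab[ok]))
  })
  counts <- sparseMatrix(
    i = unlist(lapply(trip, `[[`, "i")),
    j = unlist(lapply(trip, `[[`, "j")),
    x = unlist(lapply(trip, `[[`, "x")),
    dims = c(length(docs), length(vocab)),
    dimnames = list(doc_ids, vocab)
  )
  tfidf_weight(counts, vectorizer$idf)
}

tfidf_weight <- function(counts, idf) {
  w <- counts %*% Diagonal(x = idf)
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  out <- Diagonal(x = 1 / nrm) %*% w
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}

extract_ngrams <- function(tokens, ngram_max = 4L) {
  n <- length(tokens)
  if (n == 0) return(character())
  out <- vector("list", ngram_max)
  out[[1]] <- tokens
  for (k in 2:max(2, ngram_max)) {
    if (k > ngram_max || n < k) break
    mat <- vapply(seq_len(k), function(o) tokens[o:(n - k + o)],
                  character(n - k + 1))
    if (n - k + 1 == 1) mat <- matrix(mat, nrow = 1)
    out[[k]] <- apply(mat, 1, paste, collapse = " ")
  }
  unlist(out, use.names = FALSE)
}

#' @export
print.genelit_dtm <- function(x, ...) {
  cat("<genelit_dtm> ", x$n_docs, " documents x ", nrow(x$vocabulary),
      " n-grams (n = 1..", x$ngram_max, ")\n", sep = "")
  invisible(x)
}
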