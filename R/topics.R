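#' Fit a topic model on a document-term matrix
#'
#' Factorises the TF-IDF matrix `A` (documents x terms) into nonnegative
#' `W` (documents x K) and `H` (K x terms) with `W %*% H ~ A`.
#'
#' * `"nmf"` (default): multiplicative-update non-negative matrix
#'   factorisation under the Frobenius objective, iterated until the relative
#'   change of the reconstruction error drops below `tol` or `max_iter` is
#'   reached.
#' * `"lda"`: collapsed Gibbs sampling over the raw term counts; `W` and `H`
#'   hold the smoothed topic-assignment counts, so the same nonnegative
#'   factor interface applies (`tol` is ignored).
#'
#' @param matrix A `genelit_dtm` from [fit_vectorizer()].
#' @param K Number of topics (`1 <= K <=` number of documents).
#' @param method `"nmf"` or `"lda"`.
#' @param tol Relative-error convergence tolerance for NMF.
#' @param max_iter Iteration cap.
#' @param seed Integer seed (random initialisation / Gibbs chain).
#' @return An object of class `genelit_topics`: `W`, `H`, `K`, `method`,
#'   `vocabulary`, `doc_ids`, `err` (reconstruction-error trace, NMF).
#' @export
fit_topics <- function(matrix, K, method = c("nmf", "lda"), tol = 1e-12,
                       max_iter = 500L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "genelit_dtm"))
  A <- as.matrix(matrix$tfidf)
  if (K < 1) abort("K must be at least 1")
  if (K > nrow(A)) abort("K exceeds the number of documents")
  set.seed(seed)
  if (method == "nmf") {
    fit <- nmf_multiplicative(A, K, tol = tol, max_iter = max_iter)
  } else {
    fit <- lda_gibbs(as.matrix(matrix$counts), K, n_iter = max_iter)
  }
  structure(list(W = fit$W, H = fit$H, K = K, method = method,
                 vocabulary = matrix$vocabulary$term,
                 doc_ids = rownames(A) %||% as.character(seq_len(nrow(A))),
                 err = fit$err),
            class = "genelit_topics")
}

nmf_multiplicative <- function(A, K, tol = 1e-12, max_iter = 500L) {
  eps <- 1e-10
  n <- nrow(A); m <- ncol(A)
  W <- base::matrix(runif(n * K, 0.1, 1), n, K) * sqrt(mean(A) / K + eps)
  H <- base::matrix(runif(K * m, 0.1, 1), K, m) * sqrt(mean(A) / K + eps)
  err <- numeric()
  prev <- sqrt(sum((A - W %*% H)^2))
  err[1] <- prev
  for (it in seq_len(max_iter)) {
    H <- H * (base::crossprod(W, A)) / (base::crossprod(W, W %*% H) + eps)
    W <- W * (A %*% base::t(H)) / (W %*% base::tcrossprod(H) + eps)
    cur <- sqrt(sum((A - W %*% H)^2))
    err[it + 1] <- cur
    if (prev > 0 && abs(prev - cur) / prev < tol) break
    prev <- cur
  }
  list(W = W, H = H, err = err)
}

lda_gibbs <- function(counts, K, n_iter = 200L, alpha = 0.1, beta = 0.05) {
  counts <- round(counts)
  n <- nrow(counts); V <- ncol(counts)
  docs <- rep(seq_len(n), times = rowSums(counts))
  words <- unlist(lapply(seq_len(n), function(i) {
    rep(seq_len(V), times = counts[i, ])
  }))
  nw <- length(words)
  if (nw == 0) abort("no token occurrences for LDA")
  z <- sample(seq_len(K), nw, replace = TRUE)
  ndk <- base::matrix(0L, n, K); nkv <- base::matrix(0L, K, V); nk <- integer(K)
  for (i in seq_len(nw)) {
    ndk[docs[i], z[i]] <- ndk[docs[i], z[i]] + 1L
    nkv[z[i], words[i]] <- nkv[z[i], words[i]] + 1L
    nk[z[i]] <- nk[z[i]] + 1L
  }
  for (it in seq_len(n_iter)) {
    for (i in seq_len(nw)) {
      d <- docs[i]; v <- words[i]; k <- z[i]
      ndk[d, k] <- ndk[d, k] - 1L; nkv[k, v] <- nkv[k, v] - 1L; nk[k] <- nk[k] - 1L
      p <- (ndk[d, ] + alpha) * (nkv[, v] + beta) / (nk + V * beta)
      k <- sample.int(K, 1, prob = p)
      z[i] <- k
      ndk[d, k] <- ndk[d, k] + 1L; nkv[k, v] <- nkv[k, v] + 1L; nk[k] <- nk[k] + 1L
    }
  }
  list(W = ndk + alpha, H = nkv + beta, err = numeric())
}

#' Per-year topic timeline
#'
#' Normalises document-topic strengths to per-document probabilities (rows
#' sum to 1) and summarises their mean and standard deviation per calendar
#' year and topic. Years with no documents are omitted.
#'
#' @param model A `genelit_topics` fit.
#' @param years Per-document calendar years, aligned with the fitted
#'   documents.
#' @return A tibble (class `genelit_timeline`): `year`, `topic`, `mean`,
#'   `sd`.
#' @export
topic_timeline <- function(model, years) {
  W <- model$W
  stopifnot(length(years) == nrow(W))
  rs <- base::rowSums(W)
  rs[rs == 0] <- 1
  Wn <- W / rs
  out <- list_rbind(lapply(sort(unique(years)), function(y) {
    rows <- Wn[years == y, , drop = FALSE]
    tibble(year = y, topic = seq_len(ncol(W)),
           mean = base::colMeans(rows),
           sd = apply(rows, 2, stats::sd))
  }))
  out$sd[is.na(out$sd)] <- 0
  structure(out, class = c("genelit_timeline", class(out)))
}

#' Top phrases of a topic
#'
#' Documents are hard-assigned to their argmax topic; phrases are ranked by
#' their summed TF-IDF weight within the topic's documents.
#'
#' @param model A `genelit_topics` fit.
#' @param matrix The `genelit_dtm` the model was fitted on.
#' @param topic Topic index (1-based).
#' @param n Number of phrases to return; the full ranking if larger than the
#'   vocabulary.
#' @return A tibble `term`, `weight`, ranked decreasingly.
#' @export
top_phrases <- function(model, matrix, topic, n = 10L) {
  stopifnot(inherits(model, "genelit_topics"))
  if (topic > model$K) abort("topic index exceeds K")
  assign <- apply(model$W, 1, which.max)
  sel <- which(assign == topic)
  if (length(sel) == 0) {
    warn("no documents assigned to this topic")
    return(tibble(term = character(), weight = numeric()))
  }
  w <- Matrix::colSums(matrix$tfidf[sel, , drop = FALSE])
  out <- tibble(term = matrix$vocabulary$term, weight = as.numeric(w)) |>
    arrange(dplyr::desc(.data$weight), .data$term)
  head(out, n)
}

#' @export
print.genelit_topics <- function(x, ...) {
  cat("<genelit_topics> ", x$method, " fit, K = ", x$K, ", ",
      length(x$doc_ids), " documents x ", length(x$vocabulary), " terms\n",
      sep = "")
  invisible(x)
}
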