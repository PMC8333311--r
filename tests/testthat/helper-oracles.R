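# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# TF-IDF oracle: raw counts, smoothed add-one IDF, L2 row normalisation.
oracle_tfidf <- function(token_docs, ngram_max = 4, min_count = 2, max_df = 0.6) {
  grams_of <- function(toks) {
    out <- character()
    for (k in seq_len(ngram_max)) {
      if (length(toks) < k) break
      for (i in seq_len(length(toks) - k + 1)) {
        out <- c(out, paste(toks[i:(i + k - 1)], collapse = " "))
      }
    }
    out
  }
  per_doc <- lapply(token_docs, grams_of)
  all_terms <- sort(unique(unlist(per_doc)))
  counts <- sapply(all_terms, function(tm) {
    sum(vapply(per_doc, function(g) sum(g == tm), numeric(1)))
  })
  dfreq <- sapply(all_terms, function(tm) {
    sum(vapply(per_doc, function(g) tm %in% g, logical(1)))
  })
  n <- length(token_docs)
  keep <- all_terms[counts >= min_count & dfreq / n < max_df]
  idf <- log((1 + n) / (1 + dfreq[keep])) + 1
  mat <- t(vapply(per_doc, function(g) {
    tf <- vapply(keep, function(tm) sum(g == tm), numeric(1))
    w <- tf * idf
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w / nrm else w
  }, numeric(length(keep))))
  colnames(mat) <- keep
  mat
}

# co-citation oracle: enumerate all (citing, a, b) triples
oracle_cocitation <- function(citations, candidates) {
  citers <- unique(citations$citing)
  res <- list()
  for (c_id in citers) {
    cited <- sort(unique(citations$cited[citations$citing == c_id]))
    cited <- cited[cited %in% candidates]
    if (length(cited) < 2) next
    prs <- utils::combn(cited, 2)
    for (j in seq_len(ncol(prs))) {
      key <- paste(prs[1, j], prs[2, j], sep = "\r")
      res[[key]] <- (res[[key]] %||% 0) + 1
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(a = character(), b = character(), weight = integer()))
  }
  parts <- strsplit(names(res), "\r", fixed = TRUE)
  tibble::tibble(a = vapply(parts, `[[`, "", 1),
                 b = vapply(parts, `[[`, "", 2),
                 weight = as.integer(unlist(res))) |>
    dplyr::arrange(a, b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# dense PageRank oracle
oracle_pagerank <- function(citations, nodes, damping = 0.85, iters = 3000) {
  nodes <- sort(nodes)
  n <- length(nodes)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(citations))) {
    i <- match(citations$citing[k], nodes); j <- match(citations$cited[k], nodes)
    if (!is.na(i) && !is.na(j) && i != j) A[i, j] <- 1
  }
  M <- matrix(1 / n, n, n)
  for (i in seq_len(n)) if (sum(A[i, ]) > 0) M[i, ] <- A[i, ] / sum(A[i, ])
  p <- rep(1 / n, n)
  for (it in seq_len(iters)) p <- as.numeric((1 - damping) / n + damping * t(M) %*% p)
  tibble::tibble(pub_id = nodes, score = p / sum(p))
}

# NMI oracle from a 2x2 contingency table of counts
oracle_nmi_2x2 <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p <- c(n00, n01, n10, n11) / n
  px <- c(p[1] + p[2], p[3] + p[4])
  py <- c(p[1] + p[3], p[2] + p[4])
  h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hx <- h(px); hy <- h(py)
  if (hx == 0 || hy == 0) return(0)
  pj <- matrix(p, 2, 2)  # [x=0|1, y=0|1] column-major: p00 p01 p10 p11
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    pij <- matrix(c(p[1], p[3], p[2], p[4]), 2, 2)[i, j]
    if (pij > 0) mi <- mi + pij * log(pij / (px[i] * py[j]))
  }
  mi / sqrt(hx * hy)
}

# surface-variant enumeration oracle for fuzzy synonym matching:
# all separator choices in {"", "-", " ", "/"} between alphanumeric runs,
# matched token-bounded and case-insensitively
oracle_mentions <- function(text, synonym) {
  runs <- regmatches(synonym, gregexpr("[[:alnum:]]+", synonym))[[1]]
  seps <- c("", "-", " ", "/")
  variants <- Reduce(function(acc, run) {
    unlist(lapply(acc, function(a) paste0(a, seps, run)))
  }, runs[-1], init = runs[1])
  lt <- tolower(text)
  hit <- FALSE
  for (v in tolower(variants)) {
    start <- 1
    repeat {
      i <- regexpr(v, substr(lt, start, nchar(lt)), fixed = TRUE)
      if (i == -1) break
      pos <- start + i - 1
      before <- if (pos == 1) "" else substr(lt, pos - 1, pos - 1)
      after_pos <- pos + nchar(v)
      after <- if (after_pos > nchar(lt)) "" else substr(lt, after_pos, after_pos)
      if (!grepl("[[:alnum:]]", before) && !grepl("[[:alnum:]]", after)) {
        hit <- TRUE
        break
      }
      start <- pos + 1
    }
    if (hit) break
  }
  hit
}

# tiny corpus builder
toy_corpus <- function(...) {
  recs <- list(...)
  dplyr::bind_rows(lapply(recs, function(r) {
    tibble::tibble(
      pub_id = r$pub_id, title = r$title %||% "",
      abstract = r$abstract %||% "", keywords = list(r$keywords %||% character()),
      year = r$year %||% 2000L, is_review = isTRUE(r$is_review),
      is_trial = isTRUE(r$is_trial),
      affiliations = list(r$affiliations %||% character()),
      pharma_class = r$pharma_class %||% "none")
  }))
}
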