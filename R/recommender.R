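#' PageRank over a citation subgraph
#'
#' Standard damped power iteration on the directed citation graph restricted
#' to the given nodes. Dangling mass is redistributed uniformly and the
#' scores sum to 1.
#'
#' @param citations A citation tibble (`citing`, `cited`).
#' @param nodes Character vector of node ids (a gene's publications);
#'   defaults to all ids in the edge list.
#' @param damping Damping factor (default 0.85).
#' @param tol Convergence tolerance on the L1 change (default 1e-10).
#' @param max_iter Iteration cap.
#' @return A tibble `pub_id`, `score` (summing to 1).
#' @export
pagerank <- function(citations, nodes = NULL, damping = 0.85, tol = 1e-10,
                     max_iter = 1000L) {
  citations <- as_tibble(citations)
  nodes <- sort(unique(as.character(
    nodes %||% c(citations$citing, citations$cited))))
  n <- length(nodes)
  if (n == 0) abort("subgraph is empty")
  ed <- citations |>
    filter(.data$citing %in% nodes, .data$cited %in% nodes,
           .data$citing != .data$cited) |>
    distinct()
  src <- match(ed$citing, nodes); dst <- match(ed$cited, nodes)
  outdeg <- tabulate(src, nbins = n)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    contrib <- ifelse(outdeg > 0, p / pmax(outdeg, 1), 0)
    flow <- numeric(n)
    if (length(src)) {
      agg <- rowsum(contrib[src], dst)
      flow[as.integer(rownames(agg))] <- agg[, 1]
    }
    dangling <- sum(p[outdeg == 0])
    p_new <- (1 - damping) / n + damping * (flow + dangling / n)
    if (sum(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  tibble(pub_id = nodes, score = p / sum(p))
}

#' Review coverage matrix for a gene's literature
#'
#' @param citations A citation tibble.
#' @param pubs The gene's publication ids (matrix rows).
#' @param reviews Review ids (matrix columns); defaults to all publications
#'   in the corpus flagged `is_review` that cite at least one of `pubs`.
#' @param corpus Optional corpus tibble, needed to derive `reviews`.
#' @return A binary sparse matrix publications x reviews.
#' @export
review_coverage <- function(citations, pubs, reviews = NULL, corpus = NULL) {
  citations <- as_tibble(citations)
  if (is.null(reviews)) {
    if (is.null(corpus)) abort("pass either `reviews` or `corpus`")
    rev_ids <- corpus$pub_id[corpus$is_review]
    reviews <- intersect(unique(citations$citing[citations$cited %in% pubs]),
                         rev_ids)
  }
  reviews <- sort(unique(reviews)); pubs <- sort(unique(pubs))
  ed <- citations |>
    filter(.data$citing %in% reviews, .data$cited %in% pubs) |>
    distinct()
  sparseMatrix(i = match(ed$cited, pubs), j = match(ed$citing, reviews),
               x = 1, dims = c(length(pubs), length(reviews)),
               dimnames = list(pubs, reviews))
}

#' Score single reviews by PageRank-weighted coverage
#'
#' The raw score of a review is the sum of the PageRank scores of the
#' publications it cites, normalised by the score of a hypothetical review
#' citing every publication (the full PageRank mass, 1 by construction).
#'
#' @param coverage Binary publications x reviews matrix from
#'   [review_coverage()].
#' @param pagerank_scores Tibble `pub_id`, `score` from [pagerank()], indexed
#'   like the coverage rows.
#' @return A tibble `review_id`, `score` in `[0, 1]`, sorted decreasingly.
#' @export
score_reviews <- function(coverage, pagerank_scores) {
  pr <- pagerank_scores$score[match(rownames(coverage),
                                    pagerank_scores$pub_id)]
  if (anyNA(pr)) abort("coverage rows must be indexed by the pagerank vector")
  raw <- as.numeric(Matrix::crossprod(coverage, pr))
  tibble(review_id = colnames(coverage), score = raw / sum(pr)) |>
    arrange(dplyr::desc(.data$score), .data$review_id)
}

#' Recommend combinations of reviews
#'
#' Ranks review sets of each size in `[r_min, r_max]` by PageRank-weighted
#' coverage. In `"union"` mode (default) the selected columns' row sum is
#' binarised before weighting, so multiply-cited publications are not double
#' counted and the score is the covered PageRank mass; `"literal"` mode keeps
#' the raw row sum (the printed matrix formula), which double-counts overlap.
#' All combinations are enumerated exhaustively when their number is at most
#' `max_combinations`; otherwise greedy forward selection is used and a
#' notice is emitted.
#'
#' @param coverage Binary publications x reviews matrix.
#' @param pagerank_scores Tibble `pub_id`, `score`.
#' @param r_min,r_max Combination sizes to consider (`r_min >= 1`).
#' @param mode `"union"` or `"literal"`.
#' @param topics Optional `genelit_topics` fit over the publications (rows);
#'   adds the mean topic profile of cited publications per combination.
#' @param dates Optional tibble `pub_id`, `year`; adds the mean cited year.
#' @param max_combinations Exhaustive-enumeration cap.
#' @return A tibble: `size`, `reviews` (list of review ids), `score`,
#'   `mean_year`, and `topic_profile` (list) when topics are given; sorted by
#'   decreasing score within size.
#' @export
recommend <- function(coverage, pagerank_scores, r_min = 2L, r_max = 3L,
                      mode = c("union", "literal"), topics = NULL,
                      dates = NULL, max_combinations = 1e5) {
  mode <- match.arg(mode)
  if (r_min < 1) abort("r_min must be at least 1")
  R <- ncol(coverage)
  if (r_max > R) abort("r_max exceeds the number of reviews")
  if (r_min > r_max) abort("r_min must not exceed r_max")
  pr <- pagerank_scores$score[match(rownames(coverage),
                                    pagerank_scores$pub_id)]
  if (anyNA(pr)) abort("coverage rows must be indexed by the pagerank vector")
  cov <- as.matrix(coverage)
  years <- if (!is.null(dates)) {
    dates$year[match(rownames(coverage), dates$pub_id)]
  } else NULL
  topicW <- if (!is.null(topics)) {
    W <- topics$W[match(rownames(coverage), topics$doc_ids), , drop = FALSE]
    W / pmax(base::rowSums(W), 1e-12)
  } else NULL

  combo_score <- function(cols) {
    rs <- base::rowSums(cov[, cols, drop = FALSE])
    if (mode == "union") rs <- as.numeric(rs > 0)
    sum(rs * pr) / sum(pr)
  }
  combo_row <- function(cols) {
    covered <- base::rowSums(cov[, cols, drop = FALSE]) > 0
    tibble(
      size = length(cols),
      reviews = list(colnames(cov)[cols]),
      score = combo_score(cols),
      mean_year = if (!is.null(years) && any(covered)) {
        mean(years[covered], na.rm = TRUE)
      } else NA_real_,
      topic_profile = if (!is.null(topicW)) {
        list(if (any(covered)) base::colMeans(topicW[covered, , drop = FALSE])
             else rep(NA_real_, ncol(topicW)))
      } else list(NULL)
    )
  }

  sizes <- seq(r_min, r_max)
  total <- sum(choose(R, sizes))
  rows <- list()
  if (total <= max_combinations) {
    for (r in sizes) {
      cmb <- utils::combn(R, r)
      rows <- c(rows, lapply(seq_len(ncol(cmb)), function(j) combo_row(cmb[, j])))
    }
  } else {
    inform("combination space too large; using greedy forward selection")
    chosen <- integer()
    for (step in seq_len(r_max)) {
      rest <- setdiff(seq_len(R), chosen)
      gains <- vapply(rest, function(j) combo_score(c(chosen, j)), numeric(1))
      chosen <- c(chosen, rest[which.max(gains)])
      if (step >= r_min) rows <- c(rows, list(combo_row(chosen)))
    }
  }
  out <- list_rbind(rows) |>
    group_by(.data$size) |>
    arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    ungroup()
  structure(out, class = c("genelit_recommendation", class(out)))
}
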