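#' Tidy a PU bagging ensemble
#' @param x A `genelit_pu` object.
#' @param ... Unused.
#' @return The per-example score tibble (`index`, `score`, `n_heldout`).
#' @export
tidy.genelit_pu <- function(x, ...) x$scores

#' @rdname tidy.genelit_pu
#' @export
glance.genelit_pu <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, base_model = x$base_model,
         n_scored = nrow(x$scores),
         mean_score = mean(x$scores$score))
}

#' Tidy a topic model
#' @param x A `genelit_topics` fit.
#' @param matrix Which factor to return: `"H"` (topic-term, default) or
#'   `"W"` (document-topic).
#' @param ... Unused.
#' @return A long tibble of factor weights.
#' @export
tidy.genelit_topics <- function(x, matrix = c("H", "W"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "H") {
    tidyr::expand_grid(topic = seq_len(x$K),
                       term_i = seq_along(x$vocabulary)) |>
      mutate(term = x$vocabulary[.data$term_i],
             weight = x$H[cbind(.data$topic, .data$term_i)]) |>
      select("topic", "term", "weight")
  } else {
    tidyr::expand_grid(doc_i = seq_along(x$doc_ids), topic = seq_len(x$K)) |>
      mutate(document = x$doc_ids[.data$doc_i],
             weight = x$W[cbind(.data$doc_i, .data$topic)]) |>
      select("document", "topic", "weight")
  }
}

#' @rdname tidy.genelit_topics
#' @export
glance.genelit_topics <- function(x, ...) {
  tibble(K = x$K, method = x$method, n_docs = length(x$doc_ids),
         n_terms = length(x$vocabulary),
         reconstruction_error = if (length(x$err)) last(x$err) else NA_real_,
         iterations = max(0L, length(x$err) - 1L))
}

#' Tidy a trained forecaster
#' @param x A `genelit_forecaster`.
#' @param ... Unused.
#' @return The training loss history as a tibble (`epoch`, `loss`).
#' @export
tidy.genelit_forecaster <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.genelit_forecaster
#' @export
glance.genelit_forecaster <- function(x, ...) {
  tibble(units = x$units, n_layers = x$n_layers,
         n_series = nrow(x$ids), n_validation = length(x$val_rows),
         epochs = length(x$loss_history),
         final_loss = last(x$loss_history))
}

#' Tidy a disambiguation evaluation
#' @param x A `genelit_eval` from [evaluate_against_reference()].
#' @param ... Unused.
#' @return Per-gene recall/precision tibble.
#' @export
tidy.genelit_eval <- function(x, ...) x$by_gene

#' @rdname tidy.genelit_eval
#' @export
glance.genelit_eval <- function(x, ...) x$macro
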