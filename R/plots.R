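#' Plot a topic timeline
#'
#' Mean normalised topic weight per year with a +/- 1 sd ribbon, one colour
#' per topic.
#'
#' @param object A `genelit_timeline` from [topic_timeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genelit_timeline <- function(object, ...) {
  df <- as_tibble(object) |> mutate(topic = factor(.data$topic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mean,
                                   colour = .data$topic, fill = .data$topic)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = pmin(.data$mean + .data$sd, 1)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "year", y = "topic probability",
                  colour = "topic", fill = "topic") +
    ggplot2::theme_minimal()
}

#' Plot forecast fold changes and trendiness
#'
#' Scatter of log2 fold change (predicted over realised) against trendiness,
#' facetted by category and coloured by volume bin: trendy genes sit in the
#' upper left.
#'
#' @param object A `genelit_trendiness` from [compute_trendiness()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genelit_trendiness <- function(object, ...) {
  df <- as_tibble(object) |> mutate(bin = factor(.data$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = .data$trendiness,
                                   colour = .data$bin)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "log2 fold change (predicted / realised)",
                  y = "trendiness", colour = "volume bin") +
    ggplot2::theme_minimal()
}

#' Plot realised series against forecasts
#'
#' @param series Realised long series tibble.
#' @param predictions Predicted long tibble (e.g. [forecast_series()]).
#' @param genes Optional subset of genes to show.
#' @param category Category to plot (default `"publications"`).
#' @return A ggplot object.
#' @export
plot_forecast <- function(series, predictions, genes = NULL,
                          category = "publications") {
  real <- as_tibble(series) |>
    filter(.data$category == !!category) |>
    mutate(kind = "realised")
  pred <- as_tibble(predictions) |> filter(.data$category == !!category)
  df <- bind_rows(real[c("gene", "year", "value", "kind")],
                  pred[c("gene", "year", "value", "kind")])
  if (!is.null(genes)) df <- filter(df, .data$gene %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$value,
                                   linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "year", y = "cumulative count", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a co-citation graph coloured by community
#'
#' @param graph A `genelit_cocitation` from [build_cocitation()].
#' @param partition A community tibble from [detect_communities()] (optionally
#'   labelled by [label_communities()]).
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_communities <- function(graph, partition, seed = 1L) {
  nodes <- attr(graph, "nodes") %||% unique(c(graph$a, graph$b))
  g <- igraph::graph_from_data_frame(as_tibble(graph)[c("a", "b", "weight")],
                                     directed = FALSE,
                                     vertices = data.frame(name = sort(nodes)))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
  lay <- tibble(pub_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]) |>
    left_join(partition, by = "pub_id")
  ed <- as_tibble(graph) |>
    left_join(lay |> select("pub_id", xa = "x", ya = "y"), by = c(a = "pub_id")) |>
    left_join(lay |> select("pub_id", xb = "x", yb = "y"), by = c(b = "pub_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       linewidth = .data$weight),
                          colour = "grey80") +
    ggplot2::scale_linewidth(range = c(0.1, 1), guide = "none") +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = factor(.data$community)),
                        size = 2) +
    ggplot2::labs(colour = "community") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
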