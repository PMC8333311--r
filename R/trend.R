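#' Assemble per-gene cumulative yearly series
#'
#' Builds the ten publication/citation categories per gene: `publications`,
#' `reviews`, `trials`, `pub_big_pharma`, `pub_med_pharma` count the gene's
#' annotated publications of each kind per calendar year (cumulatively);
#' `citations`, `cit_reviews`, `cit_trials`, `cit_big_pharma`,
#' `cit_med_pharma` count citation events pointing at the gene's annotated
#' publications, categorised by the *citing* publication's flags and dated by
#' the citing publication's year (a big-pharma paper citing an annotated
#' paper adds one big-pharma citation; being cited by a non-pharma paper adds
#' nothing to the pharma categories).
#'
#' @param annotations An annotation tibble (`entity`, `pub_id`).
#' @param corpus A corpus tibble tagged by [tag_affiliations()].
#' @param citations A citation tibble.
#' @param start_year First year of the grid; earlier publications fold into
#'   its cumulative baseline.
#' @param horizon_end Last year of the grid.
#' @return A long tibble `gene`, `category`, `year`, `value` (cumulative).
#' @export
assemble_series <- function(annotations, corpus, citations,
                            start_year = 1980L, horizon_end = 2019L) {
  corpus <- validate_corpus(corpus)
  years <- seq(start_year, horizon_end)
  genes <- unique(annotations$entity)
  keep <- vapply(genes, function(g) {
    sum(annotations$entity == g) > 0
  }, logical(1))
  if (!all(keep)) inform("genes with zero annotated publications excluded")
  genes <- genes[keep]

  pub_flags <- corpus |>
    select("pub_id", "year", "is_review", "is_trial", "pharma_class")
  cum_grid <- function(evt_years, flag) {
    evt <- evt_years[flag]
    evt <- pmin(pmax(evt, start_year), horizon_end + 1L)
    cumsum(tabulate(evt - start_year + 1L, nbins = length(years)))
  }

  rows <- lapply(genes, function(g) {
    ann <- unique(annotations$pub_id[annotations$entity == g])
    pubs <- pub_flags |> filter(.data$pub_id %in% ann, !is.na(.data$year))
    cits <- citations |>
      filter(.data$cited %in% ann) |>
      inner_join(pub_flags, by = c("citing" = "pub_id"))
    cats <- list(
      publications = cum_grid(pubs$year, rep(TRUE, nrow(pubs))),
      reviews = cum_grid(pubs$year, pubs$is_review),
      trials = cum_grid(pubs$year, pubs$is_trial),
      pub_big_pharma = cum_grid(pubs$year, pubs$pharma_class == "big"),
      pub_med_pharma = cum_grid(pubs$year, pubs$pharma_class == "medium"),
      citations = cum_grid(cits$year, rep(TRUE, nrow(cits))),
      cit_reviews = cum_grid(cits$year, cits$is_review),
      cit_trials = cum_grid(cits$year, cits$is_trial),
      cit_big_pharma = cum_grid(cits$year, cits$pharma_class == "big"),
      cit_med_pharma = cum_grid(cits$year, cits$pharma_class == "medium")
    )
    list_rbind(imap(cats, function(v, nm) {
      tibble(gene = g, category = nm, year = years, value = v)
    }))
  })
  list_rbind(rows)
}

#' Mean absolute scaled error
#'
#' Forecast error scaled by the error of the naive forecast that repeats the
#' last training value across the horizon; 1 is break-even with naive,
#' smaller is better.
#'
#' @param actual,predicted Realised and forecast values over the horizon.
#' @param history The training-window series (its last value defines the
#'   naive forecast).
#' @return A single number; `0` when both errors are zero, `Inf` when only
#'   the naive error is zero.
#' @examples
#' mase(c(12, 14), c(11, 13), history = c(5, 10))  # 1/3
#' @export
mase <- function(actual, predicted, history) {
  if (length(actual) != length(predicted)) abort("length mismatch between actual and predicted")
  if (length(actual) == 0) abort("empty horizon")
  if (length(history) == 0) abort("history must have at least one value")
  naive <- rep(history[length(history)], length(actual))
  num <- mean(abs(actual - predicted))
  den <- mean(abs(actual - naive))
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

#' Naive repeat-last-value forecast
#'
#' @param series Long series tibble.
#' @param train_end Last training year.
#' @return Long tibble of naive predictions over the horizon years.
#' @export
naive_forecast <- function(series, train_end = 2013L) {
  series <- as_tibble(series)
  lastv <- series |>
    filter(.data$year <= train_end) |>
    group_by(.data$gene, .data$category) |>
    summarise(lastv = .data$value[which.max(.data$year)], .groups = "drop")
  series |>
    filter(.data$year > train_end) |>
    select("gene", "category", "year") |>
    left_join(lastv, by = c("gene", "category")) |>
    mutate(value = .data$lastv, kind = "predicted") |>
    select("gene", "category", "year", "value", "kind")
}

#' Summarise forecasts into fold changes and MASE
#'
#' Joins realised and predicted series and computes, per (gene, category):
#' the final realised and predicted cumulative counts, the fold change
#' `(predicted + 1) / (realised + 1)` (a pseudo-count guards against zero
#' denominators; genes whose realised counts outstrip the forecast get fold
#' changes below 1), the MASE over the horizon, and the initial volume
#' (cumulative count at `train_end`) used for binning.
#'
#' @param series Realised long series tibble (covering both windows).
#' @param predictions Predicted long tibble (e.g. [forecast_series()] or
#'   [naive_forecast()]).
#' @param train_end Last training year.
#' @return A tibble (class `genelit_forecast_result`): `gene`, `category`,
#'   `initial`, `realised`, `predicted`, `fold_change`, `mase`.
#' @export
forecast_result <- function(series, predictions, train_end = 2013L) {
  series <- as_tibble(series)
  horizon <- series |>
    filter(.data$year > train_end) |>
    rename(actual = "value") |>
    inner_join(predictions |> rename(predicted = "value") |>
                 select("gene", "category", "year", "predicted"),
               by = c("gene", "category", "year"))
  hist_tbl <- series |>
    filter(.data$year <= train_end) |>
    group_by(.data$gene, .data$category) |>
    summarise(initial = .data$value[which.max(.data$year)], .groups = "drop")
  out <- horizon |>
    group_by(.data$gene, .data$category) |>
    arrange(.data$year, .by_group = TRUE) |>
    summarise(
      realised = last(.data$actual),
      predicted = last(.data$predicted),
      num = mean(abs(.data$actual - .data$predicted)),
      .groups = "drop"
    ) |>
    left_join(hist_tbl, by = c("gene", "category")) |>
    mutate(fold_change = (.data$predicted + 1) / (.data$realised + 1))
  mase_tbl <- horizon |>
    left_join(hist_tbl, by = c("gene", "category")) |>
    group_by(.data$gene, .data$category) |>
    arrange(.data$year, .by_group = TRUE) |>
    summarise(mase = {
      num <- mean(abs(.data$actual - .data$predicted))
      den <- mean(abs(.data$actual - .data$initial))
      if (den == 0) { if (num == 0) 0 else Inf } else num / den
    }, .groups = "drop")
  res <- out |>
    left_join(mase_tbl, by = c("gene", "category")) |>
    select("gene", "category", "initial", "realised", "predicted",
           "fold_change", "mase")
  structure(res, class = c("genelit_forecast_result", class(res)))
}

#' Compute trendiness from forecast fold changes
#'
#' Genes are split (per category) into `n_bins` volume bins by percentiles of
#' their initial cumulative count at the end of training. Within each bin a
#' Gaussian kernel density (bandwidth `bandwidth`) is fitted to the log2 fold
#' changes, and a gene's trendiness is the area of the density's right tail
#' bounded on the left by the gene's own fold change:
#' `trendiness(g) = mean_i Phi((x_i - x_g) / h)`. With fold change defined as
#' predicted over realised, genes whose literature outgrew the forecast sit
#' in the left tail of their bin and receive trendiness near 1; within a bin
#' trendiness is strictly decreasing in fold change.
#'
#' @param results A [forecast_result()] tibble.
#' @param n_bins Number of volume bins (default 5: percentiles 20, 40, 60,
#'   80, 100).
#' @param bandwidth Gaussian KDE bandwidth on the log2 fold-change scale.
#' @return A tibble (class `genelit_trendiness`): `gene`, `category`, `bin`,
#'   `fold_change`, `log2_fold_change`, `trendiness`.
#' @export
compute_trendiness <- function(results, n_bins = 5L, bandwidth = 0.1) {
  results <- as_tibble(results) |>
    filter(is.finite(.data$fold_change), .data$fold_change > 0)
  if (nrow(results) < n_bins) abort("need at least n_bins genes with defined fold changes")
  out <- results |>
    group_by(.data$category) |>
    dplyr::group_split() |>
    lapply(function(df) {
      br <- unique(quantile(df$initial, probs = seq(0, 1, length.out = n_bins + 1)))
      bin <- cut(df$initial, breaks = br, include.lowest = TRUE, labels = FALSE)
      # merge undersized bins into their lower neighbour
      repeat {
        sizes <- table(bin)
        small <- names(sizes)[sizes < 2]
        if (length(small) == 0 || length(sizes) == 1) break
        warn("bin with fewer than 2 genes merged into neighbour")
        b <- as.integer(small[1])
        bins_sorted <- sort(unique(bin))
        tgt <- if (b == min(bins_sorted)) bins_sorted[bins_sorted > b][1] else
          max(bins_sorted[bins_sorted < b])
        bin[bin == b] <- tgt
      }
      df$bin <- bin
      df$log2_fold_change <- log2(df$fold_change)
      df |>
        group_by(.data$bin) |>
        mutate(trendiness = kde_right_tail(.data$log2_fold_change,
                                           .data$log2_fold_change,
                                           bandwidth)) |>
        ungroup()
    }) |>
    list_rbind() |>
    select("gene", "category", "bin", "fold_change", "log2_fold_change",
           "trendiness")
  structure(out, class = c("genelit_trendiness", class(out)))
}

#' Right-tail area of a Gaussian KDE
#'
#' Closed form for the mass of a Gaussian kernel density (points `x`,
#' bandwidth `h`) to the right of each evaluation point `at`:
#' `mean(pnorm((x - at) / h))`.
#'
#' @param at Evaluation points.
#' @param x Sample points the KDE is fitted on.
#' @param h Bandwidth.
#' @return Tail areas in `[0, 1]`.
#' @export
kde_right_tail <- function(at, x, h) {
  vapply(at, function(a) mean(pnorm((x - a) / h)), numeric(1))
}
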