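#' Build a gene synonym dictionary
#'
#' Unions synonyms per gene symbol across source tables, always including the
#' symbol itself among its synonyms, removes synonyms that are
#' string-identical (case-insensitively) to any disease name, and computes the
#' four ambiguity classes:
#'
#' * `nested` - the synonym is a word-bounded substring of another synonym in
#'   the dictionary (case-insensitive);
#' * `promiscuous` - the synonym appears under two or more symbols;
#' * `english` - the synonym (lower-cased) is in the bundled English word
#'   list;
#' * `short` - fewer than three characters.
#'
#' The result is deterministic and independent of source-table order.
#'
#' @param source_tables A data frame, path, or list of data frames/paths; each
#'   table needs columns `symbol` and `synonym` (an optional `source` column
#'   is ignored).
#' @param disease_names Optional disease dictionary from
#'   [build_disease_dictionary()] (or a character vector of disease names);
#'   synonyms identical to a disease name are removed.
#' @param english_words Optional character vector overriding the bundled
#'   English word list.
#' @return A tibble with columns `symbol`, `synonym`, `is_nested`,
#'   `is_promiscuous`, `is_english`, `is_short`, `safety` (initially
#'   `"unknown"`).
#' @export
build_gene_dictionary <- function(source_tables, disease_names = NULL,
                                  english_words = NULL) {
  if (is.data.frame(source_tables) || is.character(source_tables)) {
    source_tables <- list(source_tables)
  }
  tabs <- lapply(source_tables, function(x) {
    if (is.character(x)) x <- utils::read.delim(x, stringsAsFactors = FALSE)
    stopifnot(all(c("symbol", "synonym") %in% names(x)))
    as_tibble(x)[c("symbol", "synonym")]
  })
  dict <- list_rbind(tabs)
  if (any(!nzchar(dict$symbol))) abort("symbols must be non-empty")
  dict <- bind_rows(dict, tibble(symbol = unique(dict$symbol),
                                 synonym = unique(dict$symbol)))
  # case-preserving dedup: keep the first casing seen for each (symbol, syn)
  dict <- dict |>
    arrange(.data$symbol, .data$synonym) |>
    mutate(key = str_to_lower(.data$synonym)) |>
    distinct(.data$symbol, .data$key, .keep_all = TRUE)

  if (!is.null(disease_names)) {
    dn <- if (is.data.frame(disease_names) || inherits(disease_names, "tbl")) {
      str_to_lower(unlist(disease_names$names, use.names = FALSE))
    } else str_to_lower(as.character(disease_names))
    hit <- dict$key %in% dn
    if (any(hit)) {
      dropped_all <- setdiff(dict$symbol[hit], dict$symbol[!hit])
      dict <- dict[!hit, ]
      if (length(dropped_all)) {
        warn(paste0("all synonyms removed for: ",
                    paste(dropped_all, collapse = ", "),
                    "; retaining symbol-as-synonym"))
        dict <- bind_rows(dict, tibble(symbol = dropped_all,
                                       synonym = dropped_all,
                                       key = str_to_lower(dropped_all)))
      }
    }
  }

  english <- english_words %||% genelit_english_words()
  n_per_key <- dict |> count(.data$key, name = "n_symbols")
  dict <- dict |>
    left_join(n_per_key, by = "key") |>
    mutate(
      is_promiscuous = .data$n_symbols >= 2L,
      is_english = .data$key %in% str_to_lower(english),
      is_short = nchar(.data$synonym) < 3L
    )
  dict$is_nested <- nested_counts(dict$synonym) > 0L
  dict |>
    mutate(safety = "unknown") |>
    select("symbol", "synonym", "is_nested", "is_promiscuous", "is_english",
           "is_short", "safety") |>
    arrange(.data$symbol, .data$synonym)
}

# For each synonym, the number of *other* distinct synonyms that contain it
# as a word-bounded, case-insensitive substring.
nested_counts <- function(synonyms) {
  keys <- str_to_lower(synonyms)
  uniq <- unique(keys)
  counts <- setNames(integer(length(uniq)), uniq)
  for (u in uniq) {
    pat <- paste0("(?<![[:alnum:]])", escape_regex(u), "(?![[:alnum:]])")
    hosts <- uniq[uniq != u & nchar(uniq) > nchar(u)]
    if (length(hosts)) {
      counts[u] <- sum(str_detect(hosts, regex(pat, ignore_case = TRUE)))
    }
  }
  unname(counts[keys])
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

genelit_english_words <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "english_words.txt", package = "genelit")
      cache <<- readLines(path, encoding = "UTF-8", warn = FALSE)
    }
    cache
  }
})

#' Build a disease dictionary from an ontology export
#'
#' Reads a JSON export (an array of objects with `id`, `name`, `terms` and
#' `parents`) or an equivalent data frame. Names containing commas also get a
#' comma-reversed variant: the comma-separated segments are reversed in full,
#' so `"Insipidus, Diabetes"` adds `"Diabetes Insipidus"` and a three-segment
#' name reverses all three segments.
#'
#' @param ontology_export Path to a JSON file, or a data frame with columns
#'   `term_id`, `names` (list), `parents` (list).
#' @return A tibble with columns `term_id`, `preferred`, `names` (list,
#'   including reversed variants), `parents` (list of parent term ids).
#' @export
build_disease_dictionary <- function(ontology_export) {
  if (is.character(ontology_export)) {
    raw <- jsonlite::fromJSON(ontology_export, simplifyVector = FALSE)
    dict <- list_rbind(lapply(raw, function(r) {
      tibble(term_id = as.character(r$id),
             preferred = as.character(r$name %||% r$id),
             names = list(unique(c(as.character(r$name %||% character()),
                                   as.character(unlist(r$terms))))),
             parents = list(as.character(unlist(r$parents))))
    }))
  } else {
    dict <- as_tibble(ontology_export)
    if (!"preferred" %in% names(dict)) {
      dict$preferred <- vapply(dict$names, function(x) x[1] %||% NA_character_,
                               character(1))
    }
    dict <- dict[c("term_id", "preferred", "names", "parents")]
  }
  if (anyDuplicated(dict$term_id)) abort("duplicate ontology term ids")
  check_parent_cycles(dict)
  dict$names <- lapply(dict$names, function(nms) {
    unique(c(nms, comma_reversed(nms)))
  })
  dict
}

comma_reversed <- function(nms) {
  with_comma <- nms[str_detect(nms, ",")]
  vapply(with_comma, function(nm) {
    paste(rev(str_trim(str_split(nm, ",")[[1]])), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

check_parent_cycles <- function(dict) {
  edges <- tibble(
    child = rep(dict$term_id, lengths(dict$parents)),
    parent = unlist(dict$parents) %||% character()
  )
  if (nrow(edges) == 0) return(invisible())
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) abort("cyclic parent links in ontology")
  invisible()
}

#' Engineer synonym-safety features
#'
#' Computes, per (symbol, synonym) pair, the ambiguity features used by the
#' unsafe-synonym classifier: `total` (distinct candidate publications hit by
#' any synonym of the symbol), `contribution` (fraction of those hit by this
#' synonym), `n_chars`, `bits` (summed character information content,
#' `-log2` of each character's frequency in the corpus' titles and abstracts),
#' `n_nested` (number of other dictionary synonyms containing this synonym),
#' `p_syn_given_alt` and `p_alt_given_syn` (conditional mention probabilities
#' among candidate documents, 0 when the conditioning set is empty), and
#' `is_symbol`.
#'
#' @param dict A synonym dictionary from [build_gene_dictionary()].
#' @param corpus A corpus tibble (character frequencies are estimated from its
#'   titles and abstracts).
#' @param mentions A mention index from [find_candidates()] covering the
#'   dictionary entities.
#' @return A tibble of features, one row per dictionary entry.
#' @export
compute_safety_features <- function(dict, corpus, mentions) {
  corpus <- validate_corpus(corpus)
  char_freq <- corpus_char_freq(corpus)
  n_nested <- nested_counts(dict$synonym)

  hits <- mentions |>
    mutate(key = str_to_lower(.data$synonym)) |>
    distinct(.data$entity, .data$key, .data$pub_id)

  rows <- lapply(seq_len(nrow(dict)), function(i) {
    sym <- dict$symbol[i]
    key <- str_to_lower(dict$synonym[i])
    sym_hits <- hits[hits$entity == sym, ]
    docs_syn <- unique(sym_hits$pub_id[sym_hits$key == key])
    docs_alt <- unique(sym_hits$pub_id[sym_hits$key != key])
    total <- n_distinct(sym_hits$pub_id)
    tibble(
      total = total,
      contribution = if (total > 0) length(docs_syn) / total else 0,
      p_syn_given_alt = if (length(docs_alt) > 0) {
        length(intersect(docs_syn, docs_alt)) / length(docs_alt)
      } else 0,
      p_alt_given_syn = if (length(docs_syn) > 0) {
        length(intersect(docs_syn, docs_alt)) / length(docs_syn)
      } else 0
    )
  })
  feats <- list_rbind(rows)
  if (any(feats$total == 0)) {
    warn("some symbols have no candidate publications; their contribution and conditional probabilities are 0")
  }
  tibble(
    symbol = dict$symbol, synonym = dict$synonym,
    total = feats$total, contribution = feats$contribution,
    n_chars = nchar(dict$synonym),
    bits = char_bits(dict$synonym, char_freq),
    n_nested = n_nested,
    p_syn_given_alt = feats$p_syn_given_alt,
    p_alt_given_syn = feats$p_alt_given_syn,
    is_symbol = str_to_lower(dict$synonym) == str_to_lower(dict$symbol)
  )
}

# Character frequencies over the alphanumeric characters of titles+abstracts,
# lower-cased, with add-one smoothing for unseen characters.
corpus_char_freq <- function(corpus) {
  txt <- str_to_lower(paste(c(corpus$title, corpus$abstract), collapse = ""))
  chars <- strsplit(gsub("[^[:alnum:]]", "", txt), "")[[1]]
  if (length(chars) == 0) return(c(total = 1))
  tab <- table(chars)
  freq <- (as.numeric(tab) + 1) / (sum(tab) + length(tab) + 1)
  c(setNames(freq, names(tab)), total = sum(tab) + length(tab) + 1)
}

#' Summed character information content of synonyms
#' @param synonyms Character vector.
#' @param char_freq Frequency table from the working corpus (internal format).
#' @return Numeric vector of bits; the empty string scores 0.
#' @keywords internal
char_bits <- function(synonyms, char_freq) {
  floor_freq <- 1 / unname(char_freq["total"])
  vapply(str_to_lower(synonyms), function(s) {
    chars <- strsplit(gsub("[^[:alnum:]]", "", s), "")[[1]]
    if (length(chars) == 0) return(0)
    f <- char_freq[chars]
    f[is.na(f)] <- floor_freq
    sum(-log2(f))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify synonyms as safe or unsafe
#'
#' Scores synonyms with positive-unlabelled bagging (random-forest base
#' model), where the initial positive class is the union of the `english`,
#' `short` and `promiscuous` dictionary classes, refined over `n_rounds`
#' rounds. Each round re-runs the bagged ensemble; if a `labels` table is
#' supplied (the replacement for interactive relabelling), its entries join
#' the known positive/negative sides from the second round on. A synonym is
#' finally labelled unsafe iff any of four rules holds: (i) it is an English
#' word, (ii) it is shorter than three characters, (iii) its ensemble score
#' exceeds `threshold`, (iv) it is promiscuous. Rules (i), (ii) and (iv) are
#' classifier-independent.
#'
#' @param dict A synonym dictionary.
#' @param features The feature table from [compute_safety_features()].
#' @param threshold Classifier score threshold for rule (iii); default 0.5.
#' @param n_rounds Number of refinement rounds (default 5).
#' @param n_bags Bagging iterations per round.
#' @param labels Optional tibble (`synonym`, `label` in `"safe"`/`"unsafe"`)
#'   merged as known negatives/positives after the first round.
#' @param seed Integer seed.
#' @return The dictionary with `safety` filled and a `score` column appended.
#' @export
classify_unsafe <- function(dict, features, threshold = 0.5, n_rounds = 5L,
                            n_bags = 20L, labels = NULL, seed = 1L) {
  feats <- features |>
    select("total", "contribution", "n_chars", "bits", "n_nested",
           "p_syn_given_alt", "p_alt_given_syn", "is_symbol") |>
    mutate(is_symbol = as.numeric(.data$is_symbol))
  missing_feats <- !stats::complete.cases(feats)
  x <- as.matrix(feats)
  x[is.na(x)] <- 0

  pos0 <- which(dict$is_english | dict$is_short | dict$is_promiscuous)
  unl0 <- setdiff(seq_len(nrow(dict)), pos0)
  scores <- rep(NA_real_, nrow(dict))

  if (length(pos0) == 0 || length(unl0) == 0) {
    warn("degenerate positive/unlabelled split; skipping the classifier, rule (iii) never fires")
    scores[] <- 0
  } else {
    known_pos <- integer()
    known_neg <- integer()
    if (!is.null(labels)) {
      lab_idx <- match(str_to_lower(labels$synonym), str_to_lower(dict$synonym))
      known_pos <- lab_idx[labels$label == "unsafe" & !is.na(lab_idx)]
      known_neg <- lab_idx[labels$label == "safe" & !is.na(lab_idx)]
    }
    ens <- NULL
    for (round in seq_len(n_rounds)) {
      pos <- union(pos0, if (round > 1) known_pos else integer())
      neg <- if (round > 1) known_neg else integer()
      unl <- setdiff(seq_len(nrow(dict)), union(pos, neg))
      if (length(unl) == 0) break
      ens <- pu_bag_train(x, positives = pos, unlabelled = unl,
                          n_iterations = n_bags, base_model = "random_forest",
                          known_negatives = if (length(neg)) neg else NULL,
                          seed = seed + round)
      scores[ens$scores$index] <- ens$scores$score
    }
    scores[pos0] <- 1
    if (length(known_neg)) scores[known_neg] <- 0
  }

  unsafe <- dict$is_english | dict$is_short | dict$is_promiscuous |
    (!is.na(scores) & scores > threshold)
  if (any(missing_feats)) {
    warn("missing features for some synonyms; labelled unsafe conservatively")
    unsafe[missing_feats] <- TRUE
  }
  dict |>
    mutate(score = scores,
           safety = ifelse(unsafe, "unsafe", "safe"))
}
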