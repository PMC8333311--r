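#' Compile a fuzzy, boundary-aware matcher for a synonym
#'
#' The synonym is split into alphanumeric runs; between runs any single
#' separator from `{"", "-", " ", "/"}` is accepted, so a pattern for
#' `'ErbB-1'` matches `"erbB1"`, `"ERBB1"` and `"ErbB 1"`. Matching is
#' case-insensitive, and lookarounds forbid matches starting or ending inside
#' a longer alphanumeric token (`'STAR'` does not match inside `"START"`).
#'
#' @param synonym A non-empty synonym string.
#' @return A single PCRE pattern string (class `genelit_pattern`).
#' @export
compile_pattern <- function(synonym) {
  runs <- str_extract_all(synonym, "[[:alnum:]]+")[[1]]
  if (length(runs) == 0) {
    abort(paste0("synonym reduces to empty after normalisation: '", synonym, "'"))
  }
  pat <- paste0("(?i)(?<![[:alnum:]])",
                paste(runs, collapse = "[-/ ]?"),
                "(?![[:alnum:]])")
  structure(pat, class = c("genelit_pattern", "character"), synonym = synonym)
}

#' Find candidate publications mentioning an entity
#'
#' Scans each publication's searchable text (title, abstract and keywords,
#' concatenated with a `" ||| "` separator that no fuzzy pattern can bridge)
#' for all synonyms of the requested entities. Matches are resolved by
#' longest-match exclusivity across the *whole* dictionary: a span matched by
#' a synonym is not credited when it lies inside a strictly longer match of
#' another dictionary synonym (so `'insulin'` is not credited inside
#' `"insulin receptor"` when the longer synonym is also in the dictionary).
#'
#' @param corpus A corpus tibble.
#' @param dict A gene dictionary ([build_gene_dictionary()]) or disease
#'   dictionary ([build_disease_dictionary()]); disease dictionaries are
#'   expanded to (term_id, name) pairs with safety `"safe"`.
#' @param entity Optional entity id (gene symbol or disease term id) to
#'   restrict the scan; default scans all entities.
#' @param treat_unknown How to count synonyms whose `safety` is still
#'   `"unknown"` in the per-document safe-synonym tally.
#' @return A mention index tibble (class `genelit_mentions`): columns
#'   `entity`, `pub_id`, `synonym`, `start`, `end`, `safety`.
#' @seealso [safe_mention_counts()]
#' @export
find_candidates <- function(corpus, dict, entity = NULL,
                            treat_unknown = c("unsafe", "safe")) {
  corpus <- validate_corpus(corpus)
  treat_unknown <- match.arg(treat_unknown)
  entries <- as_dict_entries(dict)
  if (!is.null(entity)) {
    if (!entity %in% entries$entity) abort(paste0("unknown entity: ", entity))
    scan <- entries[entries$entity == entity, ]
  } else {
    scan <- entries
  }
  out_tpl <- tibble(entity = character(), pub_id = character(),
                    synonym = character(), start = integer(), end = integer(),
                    safety = character())
  if (nrow(corpus) == 0 || nrow(scan) == 0) {
    return(structure(out_tpl, class = c("genelit_mentions", class(out_tpl))))
  }

  texts <- searchable_text(corpus)

  # matches for the requested entities
  hits <- scan_synonyms(texts, corpus$pub_id, scan)
  if (nrow(hits) == 0) {
    return(structure(out_tpl, class = c("genelit_mentions", class(out_tpl))))
  }

  # longest-match exclusivity needs matches of every dictionary synonym that
  # word-contains a scanned synonym; scan those hosts on the hit documents only
  hosts <- containing_synonyms(unique(scan$synonym), unique(entries$synonym))
  cover <- hits
  if (length(hosts)) {
    host_entries <- entries[str_to_lower(entries$synonym) %in% hosts, ]
    doc_sel <- match(unique(hits$pub_id), corpus$pub_id)
    host_hits <- scan_synonyms(texts[doc_sel], corpus$pub_id[doc_sel],
                               distinct(host_entries, .data$synonym,
                                        .keep_all = TRUE))
    cover <- bind_rows(hits, host_hits)
  }
  hits <- drop_covered_matches(hits, cover)

  hits$safety <- entries_safety(hits, entries, treat_unknown)
  hits <- arrange(hits, .data$entity, .data$pub_id, .data$start)
  structure(hits, class = c("genelit_mentions", class(out_tpl)))
}

searchable_text <- function(corpus) {
  kw <- vapply(corpus$keywords, paste, character(1), collapse = " ||| ")
  paste(corpus$title, corpus$abstract, kw, sep = " ||| ")
}

scan_synonyms <- function(texts, pub_ids, entries) {
  res <- lapply(seq_len(nrow(entries)), function(i) {
    pat <- compile_pattern(entries$synonym[i])
    loc <- str_locate_all(texts, regex(as.character(pat)))
    nhit <- vapply(loc, nrow, integer(1))
    if (sum(nhit) == 0) return(NULL)
    mat <- do.call(rbind, loc[nhit > 0])
    tibble(entity = entries$entity[i],
           pub_id = rep(pub_ids[nhit > 0], nhit[nhit > 0]),
           synonym = entries$synonym[i],
           start = as.integer(mat[, 1]), end = as.integer(mat[, 2]))
  })
  out <- list_rbind(res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(entity = character(), pub_id = character(),
                  synonym = character(), start = integer(), end = integer())
  }
  out
}

# lower-cased dictionary synonyms that word-contain any of `targets`
containing_synonyms <- function(targets, all_synonyms) {
  keys <- unique(str_to_lower(all_synonyms))
  hosts <- character()
  for (tg in unique(str_to_lower(targets))) {
    pat <- paste0("(?<![[:alnum:]])", escape_regex(tg), "(?![[:alnum:]])")
    hit <- keys[keys != tg & nchar(keys) > nchar(tg) &
                  str_detect(keys, regex(pat, ignore_case = TRUE))]
    hosts <- union(hosts, hit)
  }
  hosts
}

# a match is dropped when a strictly longer match (from any synonym) covers it
drop_covered_matches <- function(hits, cover) {
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    cc <- cover[cover$pub_id == h$pub_id &
                  cover$start <= h$start & cover$end >= h$end &
                  (cover$end - cover$start) > (h$end - h$start), ]
    nrow(cc) == 0
  }, logical(1))
  hits[keep, ]
}

entries_safety <- function(hits, entries, treat_unknown) {
  key <- paste(entries$entity, str_to_lower(entries$synonym), sep = "\r")
  safety <- entries$safety
  safety[safety == "unknown"] <- treat_unknown
  lut <- setNames(safety, key)
  out <- lut[paste(hits$entity, str_to_lower(hits$synonym), sep = "\r")]
  unname(out)
}

as_dict_entries <- function(dict) {
  if (!is.null(dict$symbol)) {
    tibble(entity = dict$symbol, synonym = dict$synonym,
           safety = dict$safety %||% "unknown")
  } else if (!is.null(dict$term_id) && !is.null(dict$names)) {
    tibble(entity = rep(dict$term_id, lengths(dict$names)),
           synonym = unlist(dict$names), safety = "safe")
  } else {
    abort("dict must be a gene or disease dictionary")
  }
}

#' Per-publication count of distinct safe synonyms matched
#'
#' @param mentions A mention index from [find_candidates()].
#' @return A tibble `pub_id`, `n_safe`, `n_unsafe`, over all publications in
#'   the index.
#' @export
safe_mention_counts <- function(mentions) {
  mentions |>
    as_tibble() |>
    group_by(.data$pub_id) |>
    summarise(
      n_safe = n_distinct(str_to_lower(.data$synonym[.data$safety == "safe"])),
      n_unsafe = n_distinct(str_to_lower(.data$synonym[.data$safety == "unsafe"])),
      .groups = "drop"
    )
}
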