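#' Read a publication corpus
#'
#' Reads a corpus from either a line-delimited JSON dialect (one object per
#' line with the publication fields) or a PubMed-baseline-style XML subset
#' (elements `PMID`, `ArticleTitle`, `AbstractText`, `Keyword`, `PubDate/Year`,
#' `Affiliation`, `PublicationType`). Missing abstracts and keywords become
#' empty; writing with [write_corpus()] and re-reading is the identity on all
#' fields.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` or `"xml"`.
#' @return A corpus tibble: columns `pub_id`, `title`, `abstract`,
#'   `keywords` (list), `year`, `is_review`, `is_trial`, `affiliations`
#'   (list), `pharma_class` (`"none"`, `"big"` or `"medium"`).
#' @export
read_corpus <- function(path, format = c("jsonl", "xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  recs <- if (format == "jsonl") read_corpus_jsonl(path) else read_corpus_xml(path)
  validate_corpus(recs)
}

#' Write a corpus
#'
#' @param corpus A corpus tibble (see [read_corpus()]).
#' @param path Output path.
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "xml")) {
  format <- match.arg(format)
  corpus <- validate_corpus(corpus)
  if (format == "jsonl") write_corpus_jsonl(corpus, path) else write_corpus_xml(corpus, path)
  invisible(path)
}

#' An empty corpus tibble
#' @return A zero-row corpus tibble with the publication schema.
#' @export
empty_corpus <- function() {
  tibble(pub_id = character(), title = character(), abstract = character(),
         keywords = list(), year = integer(), is_review = logical(),
         is_trial = logical(), affiliations = list(),
         pharma_class = character())
}

validate_corpus <- function(corpus) {
  corpus <- as_tibble(corpus)
  needed <- names(empty_corpus())
  missing <- setdiff(needed, names(corpus))
  if (length(missing)) {
    abort(paste0("corpus is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(corpus$pub_id)) abort("pub_id values must be unique")
  if (nrow(corpus) > 0 && any(corpus$year < 1800 | corpus$year > 2100, na.rm = TRUE)) {
    abort("year out of range [1800, 2100]")
  }
  bad <- setdiff(unique(corpus$pharma_class), c("none", "big", "medium"))
  if (length(bad)) abort(paste0("invalid pharma_class: ", paste(bad, collapse = ", ")))
  corpus[needed]
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_corpus())
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      abort(paste0("malformed record ", i, ": not valid JSON"))
                    })
    for (field in c("pub_id", "year")) {
      if (is.null(rec[[field]])) {
        abort(paste0("malformed record ", i, ": missing field '", field, "'"))
      }
    }
    tibble(
      pub_id = as.character(rec$pub_id),
      title = as.character(rec$title %||% ""),
      abstract = as.character(rec$abstract %||% ""),
      keywords = list(as.character(rec$keywords %||% character())),
      year = as.integer(rec$year),
      is_review = isTRUE(rec$is_review),
      is_trial = isTRUE(rec$is_trial),
      affiliations = list(as.character(rec$affiliations %||% character())),
      pharma_class = as.character(rec$pharma_class %||% "none")
    )
  })
  list_rbind(recs)
}

write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      pub_id = corpus$pub_id[i], title = corpus$title[i],
      abstract = corpus$abstract[i], keywords = corpus$keywords[[i]],
      year = corpus$year[i], is_review = corpus$is_review[i],
      is_trial = corpus$is_trial[i], affiliations = corpus$affiliations[[i]],
      pharma_class = corpus$pharma_class[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
}

read_corpus_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(arts) == 0) return(empty_corpus())
  recs <- lapply(seq_along(arts), function(i) {
    a <- arts[[i]]
    txt1 <- function(xp) {
      node <- xml2::xml_find_first(a, xp)
      if (inherits(node, "xml_missing")) NA_character_ else xml2::xml_text(node)
    }
    txt_all <- function(xp) xml2::xml_text(xml2::xml_find_all(a, xp))
    pmid <- txt1(".//PMID")
    if (is.na(pmid) || !nzchar(pmid)) {
      abort(paste0("malformed record ", i, ": missing field 'PMID'"))
    }
    year_s <- txt1(".//PubDate/Year")
    year <- suppressWarnings(as.integer(year_s))
    if (is.na(year)) {
      abort(paste0("malformed record ", i, ": missing or unparsable field 'PubDate/Year'"))
    }
    ptypes <- txt_all(".//PublicationType")
    abst <- txt_all(".//Abstract/AbstractText")
    pharma <- xml2::xml_attr(a, "pharma")
    tibble(
      pub_id = pmid,
      title = txt1(".//ArticleTitle") %|na|% "",
      abstract = if (length(abst)) paste(abst, collapse = " ") else "",
      keywords = list(txt_all(".//KeywordList/Keyword")),
      year = year,
      is_review = "Review" %in% ptypes,
      is_trial = "Clinical Trial" %in% ptypes,
      affiliations = list(txt_all(".//Affiliation")),
      pharma_class = if (is.na(pharma)) "none" else pharma
    )
  })
  list_rbind(recs)
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

write_corpus_xml <- function(corpus, path) {
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(corpus))) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    if (corpus$pharma_class[i] != "none") {
      xml2::xml_set_attr(art, "pharma", corpus$pharma_class[i])
    }
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", corpus$pub_id[i])
    article <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(article, "ArticleTitle", corpus$title[i])
    if (nzchar(corpus$abstract[i])) {
      absn <- xml2::xml_add_child(article, "Abstract")
      xml2::xml_add_child(absn, "AbstractText", corpus$abstract[i])
    }
    journal <- xml2::xml_add_child(article, "Journal")
    issue <- xml2::xml_add_child(journal, "JournalIssue")
    pd <- xml2::xml_add_child(issue, "PubDate")
    xml2::xml_add_child(pd, "Year", as.character(corpus$year[i]))
    ptl <- xml2::xml_add_child(article, "PublicationTypeList")
    xml2::xml_add_child(ptl, "PublicationType", "Journal Article")
    if (corpus$is_review[i]) xml2::xml_add_child(ptl, "PublicationType", "Review")
    if (corpus$is_trial[i]) xml2::xml_add_child(ptl, "PublicationType", "Clinical Trial")
    for (aff in corpus$affiliations[[i]]) {
      ai <- xml2::xml_add_child(article, "AffiliationInfo")
      xml2::xml_add_child(ai, "Affiliation", aff)
    }
    if (length(corpus$keywords[[i]])) {
      kl <- xml2::xml_add_child(cit, "KeywordList")
      for (kw in corpus$keywords[[i]]) xml2::xml_add_child(kl, "Keyword", kw)
    }
  }
  xml2::write_xml(root, path)
}

#' Build a citation graph restricted to a corpus
#'
#' Reads a two-column (citing, cited) edge list, keeps edges whose both
#' endpoints exist in the corpus, collapses duplicates and drops
#' self-citations.
#'
#' @param edge_list Path to a TSV with columns `citing_id`, `cited_id` (a
#'   header line is detected and skipped), or a two-column data frame.
#' @param corpus A corpus tibble.
#' @return A tibble with columns `citing`, `cited`.
#' @export
build_citation_graph <- function(edge_list, corpus) {
  corpus <- validate_corpus(corpus)
  if (is.character(edge_list)) {
    lines <- readLines(edge_list, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(tibble(citing = character(), cited = character()))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != 2L)
    if (length(bad)) {
      abort(paste0("edge list line ", bad[1], " does not have two columns"))
    }
    edges <- tibble(citing = vapply(parts, `[[`, character(1), 1),
                    cited = vapply(parts, `[[`, character(1), 2))
    if (nrow(edges) > 0 && edges$citing[1] %in% c("citing_id", "citing")) {
      edges <- edges[-1, ]
    }
  } else {
    edges <- as_tibble(edge_list)
    names(edges)[1:2] <- c("citing", "cited")
  }
  edges |>
    mutate(citing = as.character(.data$citing), cited = as.character(.data$cited)) |>
    filter(.data$citing != .data$cited,
           .data$citing %in% corpus$pub_id,
           .data$cited %in% corpus$pub_id) |>
    distinct()
}

#' Tag publications with pharma affiliation classes
#'
#' Matches normalised organisation names (case-folded, punctuation stripped)
#' against each publication's affiliation strings as token-bounded substrings.
#' A publication matching any big-pharma organisation is classed `"big"`;
#' otherwise a medium match gives `"medium"`; otherwise `"none"`. The
#' operation is idempotent: classes are recomputed from the affiliation
#' strings on every call.
#'
#' @param corpus A corpus tibble.
#' @param orgs A data frame with columns `name` and `size_class`
#'   (`"big"`/`"medium"`), e.g. from [read_orgs()].
#' @return The corpus with `pharma_class` filled in.
#' @export
tag_affiliations <- function(corpus, orgs) {
  corpus <- validate_corpus(corpus)
  orgs <- as_tibble(orgs)
  stopifnot(all(c("name", "size_class") %in% names(orgs)))
  if (any(!nzchar(orgs$name))) abort("organisation names must be non-empty")
  if (anyDuplicated(orgs$name)) abort("one size_class per organisation name")
  pats <- paste0("(?<![a-z0-9])",
                 vapply(normalise_org(orgs$name), function(nm) {
                   gsub(" ", "[ ]", nm, fixed = TRUE)
                 }, character(1)),
                 "(?![a-z0-9])")
  big <- pats[orgs$size_class == "big"]
  med <- pats[orgs$size_class == "medium"]
  classes <- vapply(corpus$affiliations, function(affs) {
    if (length(affs) == 0) return("none")
    txt <- normalise_org(affs)
    if (length(big) && any(vapply(big, function(p) {
      any(str_detect(txt, regex(p))) }, logical(1)))) return("big")
    if (length(med) && any(vapply(med, function(p) {
      any(str_detect(txt, regex(p))) }, logical(1)))) return("medium")
    "none"
  }, character(1))
  corpus$pharma_class <- classes
  corpus
}

normalise_org <- function(x) {
  str_squish(str_replace_all(str_to_lower(x), "[^[:alnum:]]+", " "))
}

#' Read an organisation list
#'
#' @param path TSV with columns `name`, `size_class`.
#' @return A tibble with those columns.
#' @export
read_orgs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "size_class") %in% names(df)))
  as_tibble(df)
}
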