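#' Co-occurrence score of two annotation sets
#'
#' Fraction of publications carrying both tags among publications carrying
#' either (union normalisation); the alternative minimum normalisation is
#' available via `normalise = "min"`.
#'
#' @param annot_a,annot_b Character vectors of `pub_id`s.
#' @param normalise `"union"` (default) or `"min"`.
#' @return A number in `[0, 1]`; 0 (with a warning) when both sets are empty.
#' @export
cooccurrence <- function(annot_a, annot_b, normalise = c("union", "min")) {
  normalise <- match.arg(normalise)
  a <- unique(annot_a); b <- unique(annot_b)
  if (length(a) == 0 && length(b) == 0) {
    warn("both annotation sets are empty; co-occurrence set to 0")
    return(0)
  }
  joint <- length(intersect(a, b))
  den <- if (normalise == "union") length(union(a, b)) else
    min(length(a), length(b))
  if (den == 0) 0 else joint / den
}

#' Normalised mutual information of two annotation sets
#'
#' Treats membership in each set as a binary variable over a corpus of
#' `n_corpus` publications and returns `I(A;B) / sqrt(H(A) H(B))`; 0 when
#' either variable is constant.
#'
#' @param annot_a,annot_b Character vectors of `pub_id`s.
#' @param n_corpus Total number of publications (at least `|A union B|`).
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(annot_a, annot_b, n_corpus) {
  if (n_corpus == 0) abort("n_corpus must be positive")
  a <- unique(annot_a); b <- unique(annot_b)
  if (n_corpus < length(union(a, b))) abort("n_corpus smaller than |A union B|")
  n11 <- length(intersect(a, b))
  n10 <- length(a) - n11
  n01 <- length(b) - n11
  n00 <- n_corpus - n11 - n10 - n01
  tab <- matrix(c(n00, n01, n10, n11), 2, 2) / n_corpus
  px <- rowSums(tab); py <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- ent(px); hy <- ent(py)
  if (hx == 0 || hy == 0) return(0)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  }
  max(0, mi) / sqrt(hx * hy)
}

#' Map genes to disease-root ancestors
#'
#' Associates every disease term with its lowest ancestor directly under the
#' disease root and assigns each gene the ancestor with the largest summed
#' co-occurrence (ties broken by lexicographic term id).
#'
#' @param gene_disease_counts A tibble `gene`, `term_id`, `count`.
#' @param ontology A disease dictionary from [build_disease_dictionary()].
#' @param root The root term id; defaults to the unique term without parents.
#' @return A tibble `gene`, `parent` (ancestor term id), `count` (summed
#'   co-occurrence).
#' @export
map_gene_to_mesh_parent <- function(gene_disease_counts, ontology,
                                    root = NULL) {
  parents <- setNames(ontology$parents, ontology$term_id)
  if (is.null(root)) {
    cand <- ontology$term_id[lengths(ontology$parents) == 0]
    if (length(cand) != 1) abort("cannot infer a unique root; pass `root`")
    root <- cand
  }
  top_ancestor <- function(term) {
    # walk up until a child of the root; lexicographically smallest on ties
    seen <- character(); frontier <- term
    repeat {
      if (length(frontier) == 0) return(NA_character_)
      direct <- frontier[vapply(frontier, function(tm) {
        root %in% (parents[[tm]] %||% character())
      }, logical(1))]
      if (length(direct)) return(sort(direct)[1])
      if (any(frontier == root)) return(NA_character_)
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parents[frontier])), seen)
    }
  }
  counts <- as_tibble(gene_disease_counts)
  counts$parent <- vapply(counts$term_id, function(tm) {
    if (!tm %in% names(parents)) NA_character_ else top_ancestor(tm)
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(counts$parent)) {
    warn("terms without a path to the root were skipped")
    counts <- filter(counts, !is.na(.data$parent))
  }
  counts |>
    group_by(.data$gene, .data$parent) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    group_by(.data$gene) |>
    arrange(dplyr::desc(.data$count), .data$parent, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}
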