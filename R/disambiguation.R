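#' Build a weighted co-citation graph over a candidate set
#'
#' For every citing publication (candidate or not), each unordered pair of its
#' cited publications that lie in the candidate set gains +1 edge weight.
#' Candidates never co-cited stay as isolated nodes.
#'
#' @param citations A citation tibble (`citing`, `cited`).
#' @param candidates Character vector of candidate `pub_id`s.
#' @return A tibble (class `genelit_cocitation`) with columns `a`, `b`,
#'   `weight` (`a < b`), and the full candidate node set in attribute
#'   `nodes`.
#' @export
build_cocitation <- function(citations, candidates) {
  citations <- as_tibble(citations)
  candidates <- unique(as.character(candidates))
  ed <- citations |>
    filter(.data$cited %in% candidates) |>
    distinct(.data$citing, .data$cited)
  pairs <- ed |>
    inner_join(ed, by = "citing", relationship = "many-to-many") |>
    filter(.data$cited.x < .data$cited.y) |>
    count(a = .data$cited.x, b = .data$cited.y, name = "weight")
  structure(as_tibble(pairs), class = c("genelit_cocitation", class(pairs)),
            nodes = candidates)
}

#' Detect communities in a co-citation graph
#'
#' Greedy modularity maximisation (fast-greedy, weighted) run per connected
#' component. Nodes are inserted in sorted order so ties break
#' deterministically; isolated candidates become singleton communities.
#'
#' @param graph A `genelit_cocitation` from [build_cocitation()].
#' @return A tibble `pub_id`, `community` (integer ids, arbitrary but stable).
#' @export
detect_communities <- function(graph) {
  nodes <- sort(attr(graph, "nodes") %||% unique(c(graph$a, graph$b)))
  if (length(nodes) == 0) return(tibble(pub_id = character(), community = integer()))
  g <- igraph::graph_from_data_frame(
    as_tibble(graph)[c("a", "b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  comp <- igraph::components(g)$membership
  membership <- integer(length(nodes))
  names(membership) <- nodes
  next_id <- 1L
  for (cid in sort(unique(comp))) {
    vs <- names(comp)[comp == cid]
    sub <- igraph::induced_subgraph(g, vs)
    if (igraph::ecount(sub) == 0 || length(vs) == 2) {
      membership[vs] <- next_id
      next_id <- next_id + 1L
    } else {
      cl <- igraph::cluster_fast_greedy(
        sub, weights = igraph::E(sub)$weight)
      mem <- igraph::membership(cl)
      membership[names(mem)] <- next_id + as.integer(mem) - 1L
      next_id <- next_id + max(as.integer(mem))
    }
  }
  tibble(pub_id = nodes, community = unname(membership))
}

#' Label communities as linked or rejected
#'
#' A community is linked to the entity iff the ratio of members mentioning at
#' least one safe synonym to members mentioning only unsafe synonyms exceeds
#' `ratio_threshold` (0.1% by default). At the limit where no member is
#' unsafe-only, the community is linked iff it has at least one safe member;
#' communities with zero safe members are rejected.
#'
#' @param partition The community tibble from [detect_communities()].
#' @param mentions A mention index covering the community members.
#' @param ratio_threshold Safe/unsafe-only ratio bound; the comparison is
#'   strict.
#' @return The partition with per-community `n_safe`, `n_unsafe_only` and
#'   `label` (`"linked"`/`"rejected"`) columns.
#' @export
label_communities <- function(partition, mentions, ratio_threshold = 0.001) {
  counts <- safe_mention_counts(mentions)
  out <- partition |>
    left_join(counts, by = "pub_id") |>
    mutate(n_safe = dplyr::coalesce(.data$n_safe, 0L),
           n_unsafe = dplyr::coalesce(.data$n_unsafe, 0L)) |>
    group_by(.data$community) |>
    mutate(
      comm_safe = sum(.data$n_safe > 0),
      comm_unsafe_only = sum(.data$n_safe == 0 & .data$n_unsafe > 0)
    ) |>
    ungroup() |>
    mutate(
      label = dplyr::case_when(
        comm_safe == 0 ~ "rejected",
        comm_unsafe_only == 0 ~ "linked",
        comm_safe / comm_unsafe_only > ratio_threshold ~ "linked",
        TRUE ~ "rejected"
      )
    )
  out |>
    select("pub_id", "community", n_safe_doc = "n_safe",
           n_safe = "comm_safe", n_unsafe_only = "comm_unsafe_only", "label")
}

#' Classify disconnected candidate publications
#'
#' Disconnected candidates that mention a safe synonym are linked directly
#' (provenance `"safe-direct"`). The remaining disconnected candidates are
#' scored by positive-unlabelled bagging with a logistic base model over
#' TF-IDF n-grams of titles, abstracts and keywords: positives are the linked
#' community members, known negatives the rejected community members, and the
#' disconnected documents themselves form the unlabelled pool. When that pool
#' is smaller than `aux_min`, an auxiliary negative class of up to `aux_min`
#' publications mentioning other genes (`aux_pool`) is added. A document is
#' linked iff its mean held-out score exceeds `threshold`.
#'
#' @param corpus A corpus tibble.
#' @param linked_docs,rejected_docs Character vectors of community members by
#'   label.
#' @param disconnected Character vector of disconnected candidate ids.
#' @param mentions Mention index for the entity.
#' @param n_iterations PU bagging iterations (default 50).
#' @param threshold Link threshold on the mean score (default 0.5).
#' @param aux_pool Optional ids of publications mentioning other genes.
#' @param aux_min Size bound that triggers (and caps) the auxiliary negative
#'   class (default 1000).
#' @param seed Integer seed.
#' @return A tibble `pub_id`, `provenance`, `score` of newly linked documents.
#' @export
classify_disconnected <- function(corpus, linked_docs, rejected_docs,
                                  disconnected, mentions,
                                  n_iterations = 50L, threshold = 0.5,
                                  aux_pool = NULL, aux_min = 1000L,
                                  seed = 1L) {
  empty <- tibble(pub_id = character(), provenance = character(),
                  score = numeric())
  if (length(disconnected) == 0) return(empty)
  counts <- safe_mention_counts(mentions)
  safe_ids <- counts$pub_id[counts$n_safe > 0]
  direct <- intersect(disconnected, safe_ids)
  ambiguous <- setdiff(disconnected, safe_ids)
  out <- tibble(pub_id = direct,
                provenance = rep("safe-direct", length(direct)),
                score = rep(NA_real_, length(direct)))
  if (length(ambiguous) == 0) return(out)
  if (length(linked_docs) == 0) {
    warn("no linked community: ambiguous disconnected publications left unannotated")
    return(out)
  }

  set.seed(seed)
  aux <- character()
  if (length(ambiguous) < aux_min && length(aux_pool) > 0) {
    pool <- setdiff(aux_pool, c(linked_docs, rejected_docs, disconnected))
    aux <- sample(pool, size = min(aux_min, length(pool)))
  }

  train_ids <- unique(c(linked_docs, rejected_docs, aux))
  all_ids <- c(train_ids, ambiguous)
  sub <- corpus[match(all_ids, corpus$pub_id), ]
  texts <- vapply(seq_len(nrow(sub)), function(i) {
    paste(sub$title[i], sub$abstract[i],
          paste(sub$keywords[[i]], collapse = " "))
  }, character(1))
  vec <- fit_vectorizer(texts[seq_along(train_ids)], doc_ids = train_ids)
  x <- Matrix::rbind2(vec$tfidf,
                      dtm_transform(vec, texts[-seq_along(train_ids)],
                                    doc_ids = ambiguous))
  pos <- match(linked_docs, all_ids)
  neg <- match(c(rejected_docs, aux), all_ids)
  unl <- match(ambiguous, all_ids)
  ens <- pu_bag_train(x, positives = pos, unlabelled = unl,
                      n_iterations = n_iterations, base_model = "logistic",
                      known_negatives = if (length(neg)) neg else NULL,
                      seed = seed)
  sc <- ens$scores |> mutate(pub_id = all_ids[.data$index])
  linked_new <- sc |> filter(.data$score > threshold)
  bind_rows(out, tibble(pub_id = linked_new$pub_id,
                        provenance = "classifier",
                        score = linked_new$score))
}

#' Disambiguate an entity's candidate publications
#'
#' Full pipeline composition for one entity: candidate retrieval
#' ([find_candidates()]), co-citation construction ([build_cocitation()]),
#' community detection ([detect_communities()]), community labelling by the
#' 0.1% rule ([label_communities()]), and classification of disconnected
#' candidates ([classify_disconnected()]).
#'
#' @param corpus A corpus tibble.
#' @param citations A citation tibble.
#' @param dict A synonym dictionary with safety labels.
#' @param entity The gene symbol (or disease term id).
#' @param ratio_threshold Passed to [label_communities()].
#' @param aux_pool,n_iterations,threshold,seed Passed to
#'   [classify_disconnected()].
#' @return An annotation tibble (class `genelit_annotations`): `entity`,
#'   `pub_id`, `provenance` in `{"community", "safe-direct", "classifier"}`.
#' @export
disambiguate <- function(corpus, citations, dict, entity,
                         ratio_threshold = 0.001, n_iterations = 50L,
                         threshold = 0.5, aux_pool = NULL, seed = 1L) {
  mentions <- find_candidates(corpus, dict, entity = entity)
  empty <- structure(
    tibble(entity = character(), pub_id = character(), provenance = character()),
    class = c("genelit_annotations", class(tibble())))
  if (nrow(mentions) == 0) return(empty)
  candidates <- unique(mentions$pub_id)
  cocit <- build_cocitation(citations, candidates)
  connected <- unique(c(cocit$a, cocit$b))
  disconnected <- setdiff(candidates, connected)

  linked_docs <- character(); rejected_docs <- character()
  if (length(connected) > 0) {
    part <- detect_communities(
      structure(cocit, nodes = connected, class = class(cocit)))
    part <- label_communities(part, mentions, ratio_threshold)
    linked_docs <- part$pub_id[part$label == "linked"]
    rejected_docs <- part$pub_id[part$label == "rejected"]
  }

  extra <- classify_disconnected(corpus, linked_docs, rejected_docs,
                                 disconnected, mentions,
                                 n_iterations = n_iterations,
                                 threshold = threshold, aux_pool = aux_pool,
                                 seed = seed)
  out <- bind_rows(
    tibble(pub_id = linked_docs, provenance = rep("community", length(linked_docs))),
    extra |> select("pub_id", "provenance")
  ) |>
    mutate(entity = entity) |>
    select("entity", "pub_id", "provenance") |>
    arrange(.data$pub_id)
  structure(out, class = c("genelit_annotations", class(tibble())))
}

#' Evaluate annotations against a reference table
#'
#' Per-gene recall (`|ours intersect ref| / |ref|`) and precision
#' (`|ours intersect ref| / |ours|`), macro-averaged over genes with a
#' non-empty reference set.
#'
#' @param annotations An annotation tibble (`entity`, `pub_id`).
#' @param reference A data frame with columns `entity` (or `gene`) and
#'   `pub_id`.
#' @return A list of class `genelit_eval`: `by_gene` tibble (`entity`,
#'   `n_ref`, `n_ours`, `recall`, `precision`) and `macro` tibble (`recall`,
#'   `precision`). [tidy()] and [glance()] methods are provided.
#' @export
evaluate_against_reference <- function(annotations, reference) {
  reference <- as_tibble(reference)
  if ("gene" %in% names(reference) && !"entity" %in% names(reference)) {
    reference <- rename(reference, entity = "gene")
  }
  if (nrow(reference) == 0) abort("reference is empty")
  genes <- unique(reference$entity)
  by_gene <- list_rbind(lapply(genes, function(g) {
    ref <- unique(reference$pub_id[reference$entity == g])
    ours <- unique(annotations$pub_id[annotations$entity == g])
    hit <- length(intersect(ours, ref))
    tibble(entity = g, n_ref = length(ref), n_ours = length(ours),
           recall = hit / length(ref),
           precision = if (length(ours) > 0) hit / length(ours) else 0)
  }))
  structure(list(
    by_gene = by_gene,
    macro = tibble(recall = mean(by_gene$recall),
                   precision = mean(by_gene$precision))
  ), class = "genelit_eval")
}

#' @export
print.genelit_eval <- function(x, ...) {
  cat("<genelit_eval> macro recall ", round(x$macro$recall, 3),
      ", macro precision ", round(x$macro$precision, 3), " over ",
      nrow(x$by_gene), " genes\n", sep = "")
  invisible(x)
}
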