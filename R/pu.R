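#' Positive-unlabelled bagging
#'
#' Inductive bagging positive-unlabelled learning. Each iteration draws a
#' bootstrap sample of the unlabelled set (balanced bags: bootstrap size equals
#' the size of the positive set) and treats it as a provisional negative class,
#' optionally augmented with known negatives; a base scorer is fitted on
#' positives vs provisional negatives and used to score the unlabelled
#' examples *held out* of that bootstrap. The final score of an unlabelled
#' example is the mean over the iterations in which it was held out.
#'
#' Class balance is enforced by construction (equal-size bags) and, for the
#' logistic base model, additionally by balanced case weights.
#'
#' @param features A numeric matrix, sparse Matrix or data frame of
#'   per-example features (rows are examples).
#' @param positives Integer indices (rows) of the positive set.
#' @param unlabelled Integer indices of the unlabelled set; disjoint from
#'   `positives`.
#' @param n_iterations Number of bagging iterations (the disambiguation stage
#'   of the pipeline uses 50; synonym-safety scoring uses fewer per outer
#'   refinement round).
#' @param base_model `"logistic"` (ridge-regularised logistic regression) or
#'   `"random_forest"`.
#' @param known_negatives Optional indices always added to the negative side
#'   of every bag.
#' @param seed Integer seed; the ensemble is deterministic given it.
#' @param model_params List of base-model settings: `lambda` (ridge penalty,
#'   logistic), `ntree` and `nodesize` (random forest; the larger-leaf
#'   default regularises against memorising the few hidden positives drawn
#'   into a bag's provisional negatives).
#' @return An object of class `genelit_pu`: list with `scores` (tibble
#'   `index`, `score`, `n_heldout`), `members` (fitted scorers),
#'   `n_iterations` and `base_model`. Supports [predict()], [tidy()] and
#'   [glance()].
#' @export
pu_bag_train <- function(features, positives, unlabelled,
                         n_iterations = 50L,
                         base_model = c("logistic", "random_forest"),
                         known_negatives = NULL, seed = 1L,
                         model_params = list()) {
  base_model <- match.arg(base_model)
  if (length(unlabelled) == 0) abort("unlabelled set is empty")
  if (length(positives) == 0) abort("positive set is empty")
  if (length(intersect(positives, unlabelled)) > 0) {
    abort("positives and unlabelled sets must be disjoint")
  }
  x <- as_feature_matrix(features)
  params <- utils::modifyList(list(lambda = 1e-2, ntree = 200L, nodesize = 10L),
                              model_params)

  set.seed(seed)
  members <- vector("list", n_iterations)
  score_sum <- setNames(numeric(length(unlabelled)), unlabelled)
  heldout_n <- setNames(integer(length(unlabelled)), unlabelled)

  for (it in seq_len(n_iterations)) {
    bag <- sample(unlabelled, size = length(positives), replace = TRUE)
    neg <- unique(c(bag, known_negatives))
    fit <- fit_base_scorer(x, positives, neg, base_model, params)
    members[[it]] <- fit
    held <- setdiff(unlabelled, bag)
    if (length(held) > 0) {
      s <- score_base(fit, x[held, , drop = FALSE])
      key <- as.character(held)
      score_sum[key] <- score_sum[key] + s
      heldout_n[key] <- heldout_n[key] + 1L
    }
  }

  never <- heldout_n == 0
  scores <- score_sum / pmax(heldout_n, 1L)
  if (any(never)) {
    warn(paste0(sum(never), " unlabelled example(s) never held out; ",
                "scored with the full-ensemble mean"))
    idx <- unlabelled[never]
    full <- vapply(members, function(m) {
      score_base(m, x[idx, , drop = FALSE])
    }, numeric(length(idx)))
    scores[never] <- if (length(idx) == 1) mean(full) else rowMeans(full)
  }

  structure(list(
    scores = tibble(index = unlabelled, score = unname(scores),
                    n_heldout = unname(heldout_n)),
    members = members,
    n_iterations = n_iterations,
    base_model = base_model
  ), class = "genelit_pu")
}

#' @export
predict.genelit_pu <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  s <- vapply(object$members, function(m) score_base(m, x), numeric(nrow(x)))
  if (nrow(x) == 1) mean(s) else rowMeans(s)
}

as_feature_matrix <- function(features) {
  if (inherits(features, "genelit_dtm")) return(features$tfidf)
  if (is.data.frame(features)) return(as.matrix(features))
  features
}

fit_base_scorer <- function(x, pos, neg, base_model, params) {
  idx <- c(pos, neg)
  y <- factor(rep(c(1L, 0L), c(length(pos), length(neg))), levels = c(0, 1))
  xt <- x[idx, , drop = FALSE]
  if (base_model == "logistic") {
    w <- ifelse(y == 1, 0.5 / length(pos), 0.5 / length(neg)) * length(idx)
    fit <- glmnet::glmnet(xt, y, family = "binomial", alpha = 0,
                          lambda = params$lambda, weights = w,
                          standardize = FALSE)
    list(kind = "logistic", fit = fit, lambda = params$lambda)
  } else {
    xd <- as.matrix(xt)
    fit <- randomForest::randomForest(x = xd, y = y, ntree = params$ntree,
                                      nodesize = params$nodesize)
    list(kind = "random_forest", fit = fit)
  }
}

score_base <- function(member, xnew) {
  if (member$kind == "logistic") {
    as.numeric(predict(member$fit, newx = xnew, s = member$lambda,
                       type = "response"))
  } else {
    unname(predict(member$fit, newdata = as.matrix(xnew),
                   type = "prob")[, "1"])
  }
}

#' @export
print.genelit_pu <- function(x, ...) {
  cat("<genelit_pu> ", x$n_iterations, " ", x$base_model, " bags; ",
      nrow(x$scores), " unlabelled examples scored\n", sep = "")
  invisible(x)
}
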