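# Canonical subject order: sort rows lexicographically by label then feature
# values, so every output is invariant to permutations of the input rows.
canonical_order <- function(X, y) {
  do.call(order, c(list(as.integer(y)), lapply(seq_len(ncol(X)), function(j) X[, j])))
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

check_xy <- function(X, y, n_folds) {
  if (!is.matrix(X) || is.null(colnames(X))) stop("X must be a matrix with column names")
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (length(unique(y)) != 2L) stop("y must contain exactly two classes")
  if (nrow(X) < n_folds) stop("need at least n_folds subjects")
  if (min(table(y)) < n_folds) stop("each class needs at least n_folds subjects")
  invisible(NULL)
}

#' Cross-validated extremely-randomized-trees feature importance
#'
#' Fits an extremely randomized trees ensemble (each tree grown on all
#' training data, no bagging; one random split point per candidate feature) on
#' the training portion of each of `n_folds` stratified cross-validation
#' folds, extracts impurity-decrease importances, normalizes them to sum to 1
#' within each fold, and averages across folds. Subjects are re-sorted to a
#' canonical order internally, so results do not depend on row order.
#'
#' @param X Numeric matrix, subjects x regions, with region labels as column
#'   names.
#' @param y Binary class labels (positive = disease).
#' @param n_folds Number of CV folds (default 10).
#' @param n_trees Trees per ensemble (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(ncol(X)))`.
#' @param seed Integer seed; identical inputs and seed reproduce the result
#'   exactly.
#' @return List of class `importance_result`: `importance` (data.frame with
#'   `label`, `mean_importance`, `sd_importance`, sorted by decreasing mean),
#'   `n_folds`, `seed`.
#' @export
cv_feature_importance <- function(X, y, n_folds = 10, n_trees = 500,
                                  mtry = NULL, seed = 1) {
  check_xy(X, y, n_folds)
  if (all(apply(X, 2L, stats::var) == 0)) {
    stop("constant feature matrix: importances undefined")
  }
  yb <- as_binary_labels(y)
  ord <- canonical_order(X, yb)
  X <- X[ord, , drop = FALSE]
  yb <- yb[ord]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  folds <- stratified_folds(yb, n_folds)
  imp <- matrix(NA_real_, n_folds, ncol(X), dimnames = list(NULL, colnames(X)))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- ranger::ranger(
      x = as.data.frame(X[tr, , drop = FALSE]),
      y = factor(yb[tr], levels = c(FALSE, TRUE)),
      num.trees = n_trees, mtry = mtry,
      splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1,
      importance = "impurity", min.node.size = 1L,
      num.threads = 1L, seed = seed + f, verbose = FALSE
    )
    v <- fit$variable.importance
    imp[f, names(v)] <- pmax(v, 0) / sum(pmax(v, 0))
  }
  res <- data.frame(
    label = colnames(X),
    mean_importance = colMeans(imp),
    sd_importance = apply(imp, 2L, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res <- res[order(-res$mean_importance, res$label), ]
  rownames(res) <- NULL
  structure(list(importance = res, n_folds = n_folds, seed = seed),
            class = "importance_result")
}

#' Hierarchical clustering of regional SUVR features
#'
#' Clusters regions by the correlation structure of their SUVR values across
#' subjects: pairwise distance `1 - Pearson correlation`, average linkage.
#'
#' @param X Numeric matrix, subjects x regions, column names = region labels.
#' @return List of class `feature_dendrogram` with the `hclust` tree, the
#'   `labels`, and the `linkage` name.
#' @export
cluster_features <- function(X) {
  if (!is.matrix(X) || is.null(colnames(X))) stop("X must be a matrix with column names")
  if (ncol(X) < 2L) stop("need at least two regions to cluster")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance region(s): ", paste(colnames(X)[v == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(X))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, labels = colnames(X), linkage = "average"),
            class = "feature_dendrogram")
}

cv_composite_auc <- function(X, yb, members, folds) {
  score <- rowMeans(X[, members, drop = FALSE])
  n_folds <- max(folds)
  aucs <- vapply(seq_len(n_folds), function(f) {
    te <- folds == f
    auc_mw(score[te & !yb], score[te & yb])
  }, numeric(1))
  c(mean = mean(aucs), se = stats::sd(aucs) / sqrt(n_folds))
}

#' Iterative cluster-representative feature selection
#'
#' For `k = 1..K_max`, cuts the feature dendrogram into `k` clusters and picks
#' from each cluster the region with the highest mean importance (ties broken
#' by the lexicographically smallest label). Each candidate set is scored by
#' the stratified cross-validated AUC of the unweighted mean SUVR over the
#' selected regions. The chosen `k` is the smallest whose mean CV AUC is
#' within one standard error of the best one (one-standard-error rule,
#' favoring a minimalist representation).
#'
#' @param dendrogram A [cluster_features()] result.
#' @param importance A [cv_feature_importance()] result covering all leaves.
#' @param X,y As in [cv_feature_importance()].
#' @param K_max Largest number of clusters to scan; at most the leaf count.
#' @param n_folds CV folds for the evaluation score.
#' @param seed Integer seed (fold assignment).
#' @return List of class `selection_trace`: `trace` (data.frame with `k`,
#'   `score`, `score_se`, `representatives` as a list-column), `chosen_k`,
#'   `selected` (character vector of final members), `seed`.
#' @export
select_representatives <- function(dendrogram, importance, X, y, K_max,
                                   n_folds = 10, seed = 1) {
  stopifnot(inherits(dendrogram, "feature_dendrogram"),
            inherits(importance, "importance_result"))
  if (K_max > length(dendrogram$labels)) stop("K_max exceeds the number of leaves")
  imp <- importance$importance
  miss <- setdiff(dendrogram$labels, imp$label)
  if (length(miss)) stop("importance missing for: ", paste(miss, collapse = ", "))
  check_xy(X, y, n_folds)
  yb <- as_binary_labels(y)
  ord <- canonical_order(X, yb)
  X <- X[ord, , drop = FALSE]
  yb <- yb[ord]
  set.seed(seed)
  folds <- stratified_folds(yb, n_folds)
  imp_of <- stats::setNames(imp$mean_importance, imp$label)

  reps_at_k <- function(k) {
    cl <- stats::cutree(dendrogram$hclust, k = k)
    vapply(seq_len(k), function(ci) {
      labs <- sort(names(cl)[cl == ci])
      labs[which.max(imp_of[labs])]  # first max = smallest label among ties
    }, character(1))
  }
  rows <- lapply(seq_len(K_max), function(k) {
    sel <- reps_at_k(k)
    sc <- cv_composite_auc(X, yb, sel, folds)
    list(k = k, score = sc[["mean"]], score_se = sc[["se"]], representatives = sel)
  })
  score <- vapply(rows, `[[`, numeric(1), "score")
  se <- vapply(rows, `[[`, numeric(1), "score_se")
  best <- which.max(score)
  chosen_k <- min(which(score >= score[best] - se[best]))
  trace <- data.frame(k = seq_len(K_max), score = score, score_se = se)
  trace$representatives <- lapply(rows, `[[`, "representatives")
  structure(list(trace = trace, chosen_k = chosen_k,
                 selected = sort(rows[[chosen_k]]$representatives), seed = seed),
            class = "selection_trace")
}

#' Derive a data-driven composite ROI for one contrast
#'
#' Convenience wrapper chaining [cv_feature_importance()],
#' [cluster_features()] and [select_representatives()] on a regional SUVR
#' matrix, returning the selected set as an unweighted [composite_roi()]
#' together with the full selection trace.
#'
#' @inheritParams cv_feature_importance
#' @param K_max Largest number of cluster representatives scanned (default 8).
#' @param n_trees Trees per importance ensemble.
#' @param name Name for the resulting ROI.
#' @return List with `roi` ([composite_roi()]), `importance`, `dendrogram`,
#'   `selection` (the trace).
#' @export
derive_data_driven_roi <- function(X, y, K_max = 8, n_folds = 10, n_trees = 500,
                                   seed = 1, name = "data_driven") {
  importance <- cv_feature_importance(X, y, n_folds = n_folds,
                                      n_trees = n_trees, seed = seed)
  dendrogram <- cluster_features(X)
  selection <- select_representatives(dendrogram, importance, X, y,
                                      K_max = K_max, n_folds = n_folds, seed = seed)
  list(roi = composite_roi(name, selection$selected, weighting = "unweighted"),
       importance = importance, dendrogram = dendrogram, selection = selection)
}
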