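# K-nearest-neighbours with Euclidean distance, exhaustive search, and
# the documented tie rules: a split vote falls to the label of the
# single nearest neighbour, and equal distances fall to the lowest
# training index.

#' Fit (store) a K-NN model
#'
#' @param X numeric training feature matrix.
#' @param y class labels for the rows of `X`.
#' @param k number of neighbours (default 2, the study setting).
#' @return a `knn_model`.
#' @export
knn_model <- function(X, y, k = 2L) {
  X <- as.matrix(X)
  y <- as_class_factor(y)
  k <- as.integer(k)
  if (nrow(X) != length(y)) stop("X and y must have matching lengths")
  if (nrow(X) == 0L) stop("training set must be non-empty")
  if (k < 1L || k > nrow(X)) stop("k must satisfy 1 <= k <= n")
  structure(list(X = X, y = y, k = k), class = "knn_model")
}

# Indices of the k nearest training rows to query q, ordered by
# (distance, training index).
knn_neighbours <- function(model, q) {
  d2 <- colSums((t(model$X) - q)^2)
  order(d2, seq_along(d2))[seq_len(model$k)]
}

# Majority label among neighbour labels `labs` (ordered nearest-first);
# vote ties resolved by the nearest neighbour's label.
majority_label <- function(labs) {
  counts <- table(labs)
  top <- max(counts)
  winners <- names(counts)[counts == top]
  if (length(winners) == 1L) winners else as.character(labs[1L])
}

#' Predict class labels by K-NN
#'
#' @param model a [knn_model()].
#' @param X query matrix (or single feature vector).
#' @return factor of predicted labels.
#' @export
knn_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  preds <- apply(X, 1L, function(q) {
    idx <- knn_neighbours(model, q)
    majority_label(model$y[idx])
  })
  factor(preds, levels = levels(model$y))
}

#' Per-class K-NN scores
#'
#' The score of class `c` is the fraction of the `k` nearest neighbours
#' carrying label `c`; rows sum to 1. These graded scores feed the
#' one-vs-rest ROC and precision-recall curves.
#'
#' @param model a [knn_model()].
#' @param X query matrix (or single feature vector).
#' @return numeric matrix, one row per query, one column per class.
#' @export
knn_scores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  lev <- levels(model$y)
  out <- t(apply(X, 1L, function(q) {
    idx <- knn_neighbours(model, q)
    tabulate(as.integer(model$y[idx]), nbins = length(lev)) / model$k
  }))
  colnames(out) <- lev
  out
}
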