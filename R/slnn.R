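# Single-hidden-layer sigmoid network (default 7 -> 10 -> 5). Its
# sum-of-squared-errors training objective and analytic gradient are the
# function/gradient pair handed to every optimizer.

#' Network shape and weight-vector length
#'
#' The flattened weight vector has length
#' `d = (n_in + 1) * n_hidden + (n_hidden + 1) * n_out`
#' (135 for the default 7/10/5 network). Packing order: for each hidden
#' unit its `n_in` input weights followed by its bias (row-major), then
#' for each output unit its `n_hidden` weights followed by its bias.
#'
#' @param n_in number of inputs (features).
#' @param n_hidden number of hidden sigmoid units (default 10).
#' @param n_out number of outputs (classes).
#' @return a `network_shape` list with field `d`.
#' @export
network_shape <- function(n_in = 7L, n_hidden = 10L, n_out = 5L) {
  n_in <- as.integer(n_in); n_hidden <- as.integer(n_hidden); n_out <- as.integer(n_out)
  if (min(n_in, n_hidden, n_out) < 1L) stop("all layer sizes must be positive")
  structure(list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                 d = (n_in + 1L) * n_hidden + (n_hidden + 1L) * n_out),
            class = "network_shape")
}

unpack_weights <- function(w, shape) {
  if (length(w) != shape$d) {
    stop(sprintf("weight vector has length %d; shape requires %d", length(w), shape$d))
  }
  n1 <- (shape$n_in + 1L) * shape$n_hidden
  list(
    W1 = matrix(w[seq_len(n1)], nrow = shape$n_hidden, byrow = TRUE),
    W2 = matrix(w[(n1 + 1L):shape$d], nrow = shape$n_out, byrow = TRUE)
  )
}

pack_weights <- function(W1, W2) c(as.vector(t(W1)), as.vector(t(W2)))

#' Forward pass of the network
#'
#' Hidden units: `h_j = logistic(sum_i w1_ji x_i + b1_j)`; outputs:
#' `o_c = logistic(sum_j w2_cj h_j + b2_c)`. All outputs lie in (0, 1).
#'
#' @param w flattened weight vector of length `shape$d`.
#' @param X input matrix (rows are observations) or a single vector.
#' @param shape a [network_shape()].
#' @return matrix of outputs, one row per input row.
#' @export
slnn_forward <- function(w, X, shape = network_shape()) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != shape$n_in) stop("input has ", ncol(X), " columns; shape expects ", shape$n_in)
  wm <- unpack_weights(w, shape)
  H <- stats::plogis(cbind(X, 1) %*% t(wm$W1))
  stats::plogis(cbind(H, 1) %*% t(wm$W2))
}

# One-hot encode a class factor as an n x n_out matrix.
one_hot <- function(y) {
  y <- as.factor(y)
  T <- matrix(0, nrow = length(y), ncol = nlevels(y),
              dimnames = list(NULL, levels(y)))
  T[cbind(seq_along(y), as.integer(y))] <- 1
  T
}

#' Sum-of-squares training error
#'
#' `f(w) = sum over rows and classes of (output - one-hot target)^2`.
#'
#' @param w flattened weight vector.
#' @param X feature matrix.
#' @param targets one-hot target matrix (same rows as `X`).
#' @param shape a [network_shape()].
#' @return non-negative scalar.
#' @export
training_error <- function(w, X, targets, shape = network_shape()) {
  if (nrow(X) == 0L) stop("training table must be non-empty")
  O <- slnn_forward(w, X, shape)
  sum((O - targets)^2)
}

#' Backpropagation gradient of the training error
#'
#' Analytic gradient of [training_error()]; matches central finite
#' differences to high relative accuracy.
#'
#' @inheritParams training_error
#' @return gradient vector of length `shape$d`.
#' @export
training_gradient <- function(w, X, targets, shape = network_shape()) {
  if (nrow(X) == 0L) stop("training table must be non-empty")
  wm <- unpack_weights(w, shape)
  Xb <- cbind(X, 1)
  H <- stats::plogis(Xb %*% t(wm$W1))
  Hb <- cbind(H, 1)
  O <- stats::plogis(Hb %*% t(wm$W2))
  dZ2 <- 2 * (O - targets) * O * (1 - O)
  GW2 <- t(dZ2) %*% Hb
  dH <- dZ2 %*% wm$W2[, seq_len(shape$n_hidden), drop = FALSE]
  dZ1 <- dH * H * (1 - H)
  GW1 <- t(dZ1) %*% Xb
  pack_weights(GW1, GW2)
}

#' Bundle a feature matrix and labels into a training problem
#'
#' Returns the objective `f`, gradient `g`, dimension `d`, shape and
#' class levels in the form the optimizers consume.
#'
#' @param X numeric feature matrix (already standardized by the caller).
#' @param y class labels (factor or character).
#' @param n_hidden hidden-layer width (default 10).
#' @return list with elements `f`, `g`, `d`, `shape`, `levels`.
#' @export
slnn_problem <- function(X, y, n_hidden = 10L) {
  X <- as.matrix(X)
  y <- as_class_factor(y)
  if (nrow(X) != length(y)) stop("X and y must have matching lengths")
  shape <- network_shape(n_in = ncol(X), n_hidden = n_hidden, n_out = nlevels(y))
  targets <- one_hot(y)
  list(
    f = function(w) training_error(w, X, targets, shape),
    g = function(w) training_gradient(w, X, targets, shape),
    d = shape$d, shape = shape, levels = levels(y)
  )
}

#' Predict class labels with a trained network
#'
#' Argmax over the output units; exact ties go to the lowest class
#' index.
#'
#' @param w flattened weight vector.
#' @param X feature matrix (or single vector).
#' @param shape a [network_shape()].
#' @param levels class level names in canonical order.
#' @return factor of predicted labels.
#' @export
slnn_predict <- function(w, X, shape = network_shape(),
                         levels = BONN_CLASSES) {
  O <- slnn_forward(w, X, shape)
  if (length(levels) != shape$n_out) stop("levels must match the number of outputs")
  factor(levels[max.col(O, ties.method = "first")], levels = levels)
}
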