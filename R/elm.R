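#' Initialise an extreme learning machine
#'
#' Single-hidden-layer feed-forward network whose input weights `W` (H x J)
#' and biases `k` (length H) are drawn uniformly from `[-1, 1]` and then
#' frozen; only the hidden-to-output weights `beta` are learned, in closed
#' form. Supported activations: `"sigmoid"` (default), `"tanh"`, `"relu"`.
#'
#' @param J input dimension.
#' @param H number of hidden units.
#' @param O output dimension.
#' @param activation activation function name.
#' @param seed RNG seed for the random weights.
#' @return an object of class `elm_model` with `beta = NULL` until trained.
#' @export
init_elm <- function(J, H, O = 2L, activation = "sigmoid", seed = NULL) {
  stopifnot(J >= 1, H >= 1, O >= 1)
  act <- elm_activation(activation)
  W <- run_seeded(seed, matrix(stats::runif(H * J, -1, 1), H, J))
  k <- if (is.null(seed)) stats::runif(H, -1, 1) else
    run_seeded(seed + 1L, stats::runif(H, -1, 1))
  structure(list(W = W, k = k, activation = activation, beta = NULL,
                 J = as.integer(J), H = as.integer(H), O = as.integer(O),
                 seed = seed, center = NULL, scale = NULL),
            class = "elm_model")
}

elm_activation <- function(name) {
  switch(name,
         sigmoid = function(t) 1 / (1 + exp(-t)),
         tanh = base::tanh,
         relu = function(t) pmax(t, 0),
         stop(sprintf("unknown activation '%s'; supported: sigmoid, tanh, relu", name)))
}

#' Hidden-layer output matrix
#'
#' `Z[n, i] = b(w_i . x_n + k_i)` for every sample n and hidden unit i.
#'
#' @param model an [init_elm] model.
#' @param X N x J feature matrix.
#' @return N x H matrix.
#' @export
hidden_matrix <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$J) {
    stop(sprintf("dimension mismatch: X has %d columns, model expects %d",
                 ncol(X), model$J))
  }
  act <- elm_activation(model$activation)
  act(sweep(X %*% t(model$W), 2, model$k, "+"))
}

#' Moore-Penrose pseudoinverse
#'
#' SVD-based generalised inverse; singular values below `tol * max(sv)` are
#' treated as zero, so rank-deficient matrices are handled without
#' regularisation. Satisfies the four Penrose conditions.
#'
#' @param Z numeric matrix.
#' @param tol relative singular-value cutoff (default 1e-12).
#' @return the pseudoinverse, `ncol(Z) x nrow(Z)`.
#' @export
moore_penrose_pinv <- function(Z, tol = 1e-12) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("matrix contains non-finite entries")
  if (all(Z == 0)) return(t(Z))
  sv <- svd(Z)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(Z), nrow(Z)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Train an ELM by pseudoinverse solve
#'
#' `beta = Z^dagger d`: the minimum-norm least-squares solution of
#' `Z beta = d`, with Z the hidden-layer matrix on the training inputs.
#'
#' @param model an [init_elm] model.
#' @param X N x J training features.
#' @param d N x O target matrix (one-hot rows for classification).
#' @return the model with `beta` set.
#' @export
train_elm <- function(model, X, d) {
  X <- as.matrix(X); d <- as.matrix(d)
  if (nrow(X) == 0) stop("empty training set")
  if (nrow(X) != nrow(d)) stop("X and d row counts differ")
  if (anyNA(X) || anyNA(d)) stop("training data contains missing values")
  Xs <- elm_scale(model, X)
  Z <- hidden_matrix(model, Xs)
  model$beta <- moore_penrose_pinv(Z) %*% d
  model$O <- ncol(d)
  model
}

elm_scale <- function(model, X) {
  if (is.null(model$center)) return(X)
  sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
}

#' Set feature standardisation on an ELM
#'
#' Stores per-feature centre/scale (train-set mean and SD; SD 0 becomes 1)
#' applied before the hidden layer in both training and prediction.
#'
#' @param model an [init_elm] model.
#' @param X feature matrix to compute the statistics from.
#' @return the model with scaling attached.
#' @export
elm_set_scaling <- function(model, X) {
  X <- as.matrix(X)
  model$center <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  model$scale <- ifelse(s > 0, s, 1)
  model
}

#' Predict with a trained ELM
#'
#' `Y = Z beta`; the class label is the argmax over output columns
#' (0-based), ties broken by the lowest index.
#'
#' @param object a trained [elm_model].
#' @param X feature matrix.
#' @param ... unused.
#' @return list with `Y` (N x O score matrix) and `class` (0-based labels).
#' @export
predict.elm_model <- function(object, X, ...) {
  if (is.null(object$beta)) stop("untrained model: beta is unset; call train_elm() first")
  Xs <- elm_scale(object, as.matrix(X))
  Y <- hidden_matrix(object, Xs) %*% object$beta
  list(Y = Y, class = max.col(Y, ties.method = "first") - 1L)
}

#' One-hot encode binary/integer class labels
#'
#' @param labels integer vector of 0-based class labels.
#' @param n_classes number of classes (default from data).
#' @return N x n_classes 0/1 matrix with unit row sums.
#' @export
one_hot <- function(labels, n_classes = max(labels) + 1L) {
  d <- matrix(0, length(labels), n_classes)
  d[cbind(seq_along(labels), labels + 1L)] <- 1
  d
}

#' Serialize / restore an ELM model as JSON
#'
#' @param model a trained or untrained [elm_model].
#' @param path file path.
#' @export
write_elm <- function(model, path) {
  obj <- list(W = model$W, k = model$k, activation = model$activation,
              beta = model$beta, J = model$J, H = model$H, O = model$O,
              seed = model$seed, center = model$center, scale = model$scale)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(W = as.matrix(obj$W), k = as.numeric(obj$k),
                          activation = obj$activation,
                          beta = if (is.null(obj$beta)) NULL else as.matrix(obj$beta),
                          J = as.integer(obj$J), H = as.integer(obj$H),
                          O = as.integer(obj$O), seed = obj$seed,
                          center = if (is.null(obj$center)) NULL else as.numeric(obj$center),
                          scale = if (is.null(obj$scale)) NULL else as.numeric(obj$scale)),
                     class = "elm_model")
  model
}
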