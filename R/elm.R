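#' Hidden-layer output matrix
#'
#' `H[j, i] = g(w_i . x_j + b_i)`: each of the `L` hidden neurons applies
#' its activation to an affine projection of sample `j`.
#'
#' @param X `N x n` input matrix (rows = samples).
#' @param w `L x n` input-weight matrix.
#' @param b length-`L` bias vector.
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @return `N x L` matrix.
#' @export
hidden_matrix <- function(X, w, b, activation = c("sigmoid", "tanh")) {
  activation <- match.arg(activation)
  X <- as.matrix(X); w <- as.matrix(w)
  if (ncol(X) != ncol(w))
    stop("`X` and `w` disagree on the input dimension", call. = FALSE)
  if (length(b) != nrow(w))
    stop("`b` must have one entry per hidden neuron", call. = FALSE)
  Z <- X %*% t(w) + matrix(b, nrow(X), length(b), byrow = TRUE)
  switch(activation,
         sigmoid = 1 / (1 + exp(-Z)),
         tanh = tanh(Z))
}

#' Solve ELM output weights
#'
#' Minimum-norm least-squares solution `beta = H^+ T` via the Moore-Penrose
#' generalized inverse, the closed-form output layer of the extreme
#' learning machine.
#'
#' @param H `N x L` hidden-layer matrix.
#' @param T_ targets, length-`N` vector or `N x m` matrix.
#' @return `L x m` matrix of output weights.
#' @export
solve_output_weights <- function(H, T_) {
  H <- as.matrix(H)
  T_ <- as.matrix(T_)
  if (nrow(H) != nrow(T_))
    stop("`H` and targets disagree on the sample count", call. = FALSE)
  if (!all(is.finite(H))) stop("`H` must be finite", call. = FALSE)
  MASS::ginv(H) %*% T_
}

fit_scaler <- function(x) {
  r <- range(x)
  if (diff(r) <= .Machine$double.eps) r[2] <- r[1] + 1  # constant input
  list(min = r[1], range = r[2] - r[1])
}
scale_to <- function(x, s) (x - s$min) / s$range
scale_from <- function(x, s) x * s$range + s$min

#' Train an extreme learning machine
#'
#' Input weights and biases are drawn uniform on [-1, 1] from `seed` and
#' never adjusted; the output weights are solved in closed form by the
#' pseudoinverse. With min-max scaling on (the default) inputs and targets
#' are mapped to [0, 1] using the training range, which conditions the
#' sigmoid hidden layer.
#'
#' @param windows a `supervised_windows` object (see [make_windows()]), or
#'   a list with `inputs` matrix and `targets` vector.
#' @param L hidden-neuron count, >= 1 (default 20).
#' @param activation hidden activation, `"sigmoid"` or `"tanh"`.
#' @param seed integer seed for the random hidden layer.
#' @param scale logical: min-max scale inputs/targets (default `TRUE`).
#' @param weights,biases optional explicit hidden parameters (`L x n`
#'   matrix / length-`L` vector); when supplied the random draw is skipped.
#' @return An object of class `elm_model` with fields `w`, `b`, `beta`,
#'   `activation`, `L`, scalers and `training_rmse`.
#' @export
train_elm <- function(windows, L = 20, activation = c("sigmoid", "tanh"),
                      seed = 1L, scale = TRUE, weights = NULL,
                      biases = NULL) {
  activation <- match.arg(activation)
  L <- as.integer(L)
  if (L < 1) stop("`L` must be >= 1", call. = FALSE)
  X <- as.matrix(windows$inputs)
  y <- as.numeric(windows$targets)
  n_in <- ncol(X)
  x_scaler <- if (scale) fit_scaler(X) else NULL
  y_scaler <- if (scale) fit_scaler(y) else NULL
  Xs <- if (scale) scale_to(X, x_scaler) else X
  ys <- if (scale) scale_to(y, y_scaler) else y
  if (is.null(weights)) {
    hp <- with_seed(seed, list(w = matrix(runif(L * n_in, -1, 1), L, n_in),
                               b = runif(L, -1, 1)))
    weights <- hp$w; biases <- hp$b
  } else {
    weights <- matrix(as.numeric(weights), L, n_in)
    biases <- as.numeric(biases)
  }
  H <- hidden_matrix(Xs, weights, biases, activation)
  beta <- solve_output_weights(H, ys)
  pred <- as.numeric(H %*% beta)
  if (scale) pred <- scale_from(pred, y_scaler)
  model <- structure(
    list(w = weights, b = biases, beta = beta, activation = activation,
         L = L, n_inputs = n_in, x_scaler = x_scaler, y_scaler = y_scaler,
         training_rmse = sqrt(mean((pred - y)^2))),
    class = "elm_model")
  model
}

#' Predict with an ELM
#'
#' @param object an `elm_model`.
#' @param newdata matrix of inputs (rows = samples) or a
#'   `supervised_windows` object.
#' @param ... unused.
#' @return Numeric vector of predictions on the original scale.
#' @export
predict.elm_model <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$inputs))
    as.matrix(newdata$inputs) else rbind(newdata)
  X <- matrix(as.numeric(X), ncol = object$n_inputs)
  if (!is.null(object$x_scaler)) X <- scale_to(X, object$x_scaler)
  pred <- as.numeric(hidden_matrix(X, object$w, object$b,
                                   object$activation) %*% object$beta)
  if (!is.null(object$y_scaler)) pred <- scale_from(pred, object$y_scaler)
  pred
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d inputs -> %d %s neurons -> 1 output\n",
              x$n_inputs, x$L, x$activation))
  cat(sprintf("  training RMSE: %.6g\n", x$training_rmse))
  invisible(x)
}

#' Train a WOA-tuned extreme learning machine
#'
#' The whale optimization algorithm searches the flattened hidden-layer
#' parameters (input weights then biases, `L*n + L` dimensions, box
#' [-1, 1]); for every candidate the output weights are re-solved by the
#' pseudoinverse on the chronologically earlier fit portion of the windows
#' and the fitness is the RMSE on the held-out chronological tail. The
#' returned model carries the best candidate found.
#'
#' @inheritParams train_elm
#' @param n_agents,max_iter WOA population size and iteration budget
#'   (defaults 10 and 200).
#' @param val_fraction fraction of windows held out (chronological tail)
#'   for the fitness, in (0, 1); default 0.2.
#' @param seed integer seed shared by the WOA and the search.
#' @return An `elm_model` with extra fields `validation_rmse` and
#'   `woa_history`.
#' @export
train_woa_elm <- function(windows, L = 20,
                          activation = c("sigmoid", "tanh"),
                          n_agents = 10, max_iter = 200,
                          val_fraction = 0.2, seed = 1L, scale = TRUE) {
  activation <- match.arg(activation)
  L <- as.integer(L)
  X <- as.matrix(windows$inputs)
  y <- as.numeric(windows$targets)
  N <- nrow(X)
  n_in <- ncol(X)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in (0, 1)", call. = FALSE)
  n_val <- max(1L, floor(val_fraction * N))
  n_fit <- N - n_val
  if (n_fit < 1) stop("not enough windows to split off a validation tail",
                      call. = FALSE)
  x_scaler <- if (scale) fit_scaler(X[seq_len(n_fit), , drop = FALSE]) else NULL
  y_scaler <- if (scale) fit_scaler(y[seq_len(n_fit)]) else NULL
  Xs <- if (scale) scale_to(X, x_scaler) else X
  ys <- if (scale) scale_to(y, y_scaler) else y
  X_fit <- Xs[seq_len(n_fit), , drop = FALSE]
  y_fit <- ys[seq_len(n_fit)]
  X_val <- Xs[(n_fit + 1):N, , drop = FALSE]
  y_val <- y[(n_fit + 1):N]  # original scale for the reported RMSE
  dim_search <- L * n_in + L
  unpack <- function(v) list(w = matrix(v[seq_len(L * n_in)], L, n_in),
                             b = v[(L * n_in + 1):dim_search])
  fitness <- function(v) {
    hp <- unpack(v)
    H_fit <- hidden_matrix(X_fit, hp$w, hp$b, activation)
    beta <- solve_output_weights(H_fit, y_fit)
    pred <- as.numeric(hidden_matrix(X_val, hp$w, hp$b, activation) %*% beta)
    if (scale) pred <- scale_from(pred, y_scaler)
    sqrt(mean((pred - y_val)^2))
  }
  res <- woa_optimize(fitness,
                      woa_config(dim = dim_search, lower = -1, upper = 1,
                                 n_agents = n_agents, max_iter = max_iter,
                                 seed = seed))
  hp <- unpack(res$best_position)
  H_fit <- hidden_matrix(X_fit, hp$w, hp$b, activation)
  beta <- solve_output_weights(H_fit, y_fit)
  pred_tr <- as.numeric(hidden_matrix(X_fit, hp$w, hp$b, activation) %*% beta)
  if (scale) pred_tr <- scale_from(pred_tr, y_scaler)
  model <- structure(
    list(w = hp$w, b = hp$b, beta = beta, activation = activation, L = L,
         n_inputs = n_in, x_scaler = x_scaler, y_scaler = y_scaler,
         training_rmse = sqrt(mean((pred_tr - y[seq_len(n_fit)])^2)),
         validation_rmse = res$best_fitness, woa_history = res$history),
    class = "elm_model")
  model
}

#' Serialize an ELM model to a flat text file
#'
#' Plain `dput()` text of the model list; read back with [read_elm()].
#'
#' @param model an `elm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_elm <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  dput(unclass(model), file = path,
       control = c("keepNA", "keepInteger", "niceNames",
                   "showAttributes", "digits17"))
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  obj <- dget(path)
  structure(obj, class = "elm_model")
}
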