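#' Initialize a back-propagation network
#'
#' A feed-forward network with one hidden layer of logistic-sigmoid
#' neurons and a single sigmoid output.  Weights are drawn uniformly in
#' [-0.5, 0.5] from the seeded generator; biases start at 0.
#'
#' @param n_input number of input neurons (the panel size).
#' @param n_hidden hidden-layer size (default 4).
#' @param seed integer seed for the weight draw.
#' @return an object of class `ann_model`: `W1` (n_input x n_hidden),
#'   `b1`, `w2`, `b2`, `n_input`, `n_hidden`, `seed`, `scaling`
#'   (filled by [ann_train()]).
#' @export
ann_init <- function(n_input, n_hidden = 4, seed = 1) {
  stopifnot(n_input >= 1L, n_hidden >= 1L)
  set.seed(seed)
  structure(list(
    W1 = matrix(stats::runif(n_input * n_hidden, -0.5, 0.5),
                n_input, n_hidden),
    b1 = numeric(n_hidden),
    w2 = stats::runif(n_hidden, -0.5, 0.5),
    b2 = 0,
    n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
    seed = as.integer(seed), scaling = NULL, trace = NULL,
    hyper = NULL), class = "ann_model")
}

minmax_scaling <- function(X, y) {
  x_min <- apply(X, 2L, min)
  x_max <- apply(X, 2L, max)
  x_rng <- x_max - x_min
  y_min <- min(y); y_rng <- max(y) - y_min
  list(x_min = x_min, x_rng = x_rng, y_min = y_min, y_rng = y_rng)
}

scale_inputs <- function(X, sc) {
  out <- sweep(X, 2L, sc$x_min)
  rng <- ifelse(sc$x_rng > 0, sc$x_rng, 1)
  out <- sweep(out, 2L, rng, "/")
  out[, sc$x_rng == 0] <- 0.5 - 0.1 / 0.8    # constant columns map to 0.5
  0.1 + 0.8 * out
}

scale_response <- function(y, sc) {
  if (sc$y_rng > 0) 0.1 + 0.8 * (y - sc$y_min) / sc$y_rng
  else rep(0.5, length(y))
}

unscale_response <- function(s, sc) {
  sc$y_min + (s - 0.1) / 0.8 * sc$y_rng
}

#' Train the network by online back-propagation
#'
#' Inputs and response are min-max scaled to [0.1, 0.9] (the scaling is
#' stored in the model and inverted on prediction).  Training is
#' per-pattern gradient descent with momentum, visiting the patterns in
#' a freshly shuffled order each epoch (the shuffle draws from R's RNG,
#' so `set.seed()` before the call, or the `seed` argument, makes
#' training exactly reproducible).  The trace records the Eq-1 RMS in
#' original cell-count units after each recorded epoch, on the training
#' set and, if given, on a verification set.
#'
#' @param model an [ann_init()] model.
#' @param X numeric matrix (or [intensity_matrix()] at stage
#'   `"selected"`), rows matched to `y`.
#' @param y contaminant cell counts.
#' @param epochs training cycles (default 3000).
#' @param learning_rate,momentum back-propagation hyperparameters
#'   (defaults 0.01 and 0.9).
#' @param trace_every record the trace every this many epochs (0 = final
#'   epoch only; default 1).
#' @param verification optional list(X, y) held-out set traced alongside.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   before training so the pattern shuffles are reproducible.
#' @return the trained `ann_model`, with `$trace` (data.frame `epoch`,
#'   `train_rms` and optionally `verif_rms`) and `$scaling` filled in.
#' @export
ann_train <- function(model, X, y, epochs = 3000, learning_rate = 0.01,
                      momentum = 0.9, trace_every = 1, verification = NULL,
                      seed = NULL) {
  stopifnot(inherits(model, "ann_model"), epochs >= 1)
  if (inherits(X, "intensity_matrix")) X <- X$values
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (ncol(X) != model$n_input)
    stop("X has ", ncol(X), " columns; network expects ", model$n_input,
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sc <- minmax_scaling(X, y)
  Xs <- scale_inputs(X, sc)
  ys <- scale_response(y, sc)
  Xv <- yv <- NULL
  if (!is.null(verification)) {
    Xv <- scale_inputs(as.matrix(verification$X), sc)
    yv <- scale_response(as.numeric(verification$y), sc)
  }
  fit <- ann_train_cpp(Xs, ys, model$W1, model$b1, model$w2, model$b2,
                       as.integer(epochs), learning_rate, momentum,
                       as.integer(trace_every), sc$y_min, sc$y_rng,
                       Xv, yv)
  if (fit$diverged > 0)
    stop(sprintf("training diverged at epoch %d (learning_rate = %g)",
                 fit$diverged, learning_rate), call. = FALSE)
  model$W1 <- fit$W1
  model$b1 <- fit$b1
  model$w2 <- fit$w2
  model$b2 <- fit$b2
  model$scaling <- sc
  tr <- data.frame(epoch = fit$trace$epoch, train_rms = fit$trace$train_rms)
  if (!is.null(fit$trace$verif_rms)) tr$verif_rms <- fit$trace$verif_rms
  model$trace <- tr
  model$hyper <- list(epochs = epochs, learning_rate = learning_rate,
                      momentum = momentum)
  model
}

#' Forward pass of a trained network
#'
#' Deterministic prediction: inputs are scaled with the stored min-max
#' parameters, passed through the sigmoid layers, and the output is
#' unscaled back to cell counts.  An untrained network (all-zero
#' weights and biases) returns the midpoint of the training response
#' range for any input.
#'
#' @param model a trained `ann_model` (with `$scaling` set, or raw
#'   weights applied to unscaled inputs if not).
#' @param X matrix (or [intensity_matrix()]) with `n_input` columns.
#' @return predicted contaminant cell counts.
#' @export
ann_predict <- function(model, X) {
  stopifnot(inherits(model, "ann_model"))
  if (inherits(X, "intensity_matrix")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) != model$n_input)
    stop("X has ", ncol(X), " columns; network expects ", model$n_input,
         call. = FALSE)
  Xs <- if (!is.null(model$scaling)) scale_inputs(X, model$scaling) else X
  H <- 1 / (1 + exp(-(Xs %*% model$W1 + matrix(model$b1, nrow(Xs),
                                               model$n_hidden, byrow = TRUE))))
  o <- 1 / (1 + exp(-(drop(H %*% model$w2) + model$b2)))
  if (!is.null(model$scaling)) unscale_response(o, model$scaling) else o
}

#' Fit an ANN calibrator
#'
#' Modelling front end wrapping [ann_init()] + [ann_train()]: fits the
#' single-hidden-layer back-propagation network that maps a selected-peak
#' fingerprint to the contaminant cell count.
#'
#' @inheritParams ann_train
#' @param n_hidden hidden neurons (default 4).
#' @param seed integer seed governing both the weight initialization and
#'   the training shuffles.
#' @return an object of class `ann_calibrator` (also `ann_model`).
#' @export
ann_calibrator <- function(X, y, n_hidden = 4, epochs = 3000,
                           learning_rate = 0.01, momentum = 0.9,
                           trace_every = 0, verification = NULL, seed = 1) {
  if (inherits(X, "intensity_matrix")) X <- X$values
  model <- ann_init(ncol(X), n_hidden = n_hidden, seed = seed)
  model <- ann_train(model, X, y, epochs = epochs,
                     learning_rate = learning_rate, momentum = momentum,
                     trace_every = trace_every, verification = verification,
                     seed = seed + 1L)
  class(model) <- c("ann_calibrator", class(model))
  model
}

#' @export
#' @method predict ann_calibrator
predict.ann_calibrator <- function(object, newdata, ...) {
  ann_predict(object, newdata)
}

#' @export
#' @method print ann_model
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %d-%d-1 sigmoid network%s\n",
              x$n_input, x$n_hidden,
              if (is.null(x$scaling)) " (untrained)" else ""))
  if (!is.null(x$trace) && nrow(x$trace))
    cat(sprintf("  final training RMS: %.4g cells (epoch %d)\n",
                x$trace$train_rms[nrow(x$trace)],
                x$trace$epoch[nrow(x$trace)]))
  invisible(x)
}

#' @export
#' @method coef ann_model
coef.ann_model <- function(object, ...) {
  list(W1 = object$W1, b1 = object$b1, w2 = object$w2, b2 = object$b2)
}

#' Serialize / restore an ANN model as JSON
#'
#' The JSON records the architecture, weights, biases, min-max scaling,
#' seed and training hyperparameters, so a stored calibrator can be
#' reloaded and applied to new spectra.
#'
#' @param model a trained `ann_model`.
#' @param path JSON file path.
#' @return `write_ann_model`: `path` invisibly; `read_ann_model`: the
#'   restored `ann_model`.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(n_input = model$n_input, n_hidden = model$n_hidden,
              seed = model$seed, W1 = model$W1, b1 = model$b1,
              w2 = model$w2, b2 = model$b2, scaling = model$scaling,
              hyper = model$hyper)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- ann_init(obj$n_input, obj$n_hidden, seed = obj$seed)
  W1 <- obj$W1
  if (is.null(dim(W1)))
    W1 <- matrix(as.numeric(W1), obj$n_input, obj$n_hidden, byrow = TRUE)
  m$W1 <- matrix(as.numeric(W1), obj$n_input, obj$n_hidden)
  m$b1 <- as.numeric(obj$b1)
  m$w2 <- as.numeric(obj$w2)
  m$b2 <- as.numeric(obj$b2)
  if (!is.null(obj$scaling))
    m$scaling <- list(x_min = as.numeric(obj$scaling$x_min),
                      x_rng = as.numeric(obj$scaling$x_rng),
                      y_min = as.numeric(obj$scaling$y_min),
                      y_rng = as.numeric(obj$scaling$y_rng))
  m$hyper <- obj$hyper
  m
}
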