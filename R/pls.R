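#' Fit a PLS1 calibrator (NIPALS)
#'
#' Partial least squares projection to latent structures for a single
#' response: X and y are mean-centered, latent components are extracted
#' by the NIPALS sequence (weight = X'y direction, score, loading,
#' deflation), and the regression coefficients are assembled so that
#' prediction is linear in X.  This is the linear baseline the neural
#' calibrator is benchmarked against.
#'
#' @param X numeric matrix (or [intensity_matrix()]) of selected-peak
#'   intensities, one row per spectrum.
#' @param y contaminant cell counts, one per row.
#' @param n_components number of latent components; capped at the
#'   effective rank encountered during extraction.
#' @return an object of class `pls_calibrator` with elements
#'   `coefficients` (named vector, one per column), `x_means`, `y_mean`,
#'   `n_components` (actually used), `W`, `P`, `q`.
#' @export
pls_calibrator <- function(X, y, n_components = 5) {
  if (inherits(X, "intensity_matrix")) X <- X$values
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L)
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop("n_components must be <= min(rows - 1, columns)", call. = FALSE)
  if (all(apply(X, 2L, stats::var) == 0))
    stop("X has zero variance", call. = FALSE)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_means)
  yc <- y - y_mean
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  used <- 0L
  x_scale <- sum(Xc^2)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, x_scale)) break
    w <- w / nw
    t_sc <- drop(Xc %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-12 * max(1, x_scale)) break
    P[, a] <- drop(crossprod(Xc, t_sc)) / tt
    q[a] <- sum(yc * t_sc) / tt
    W[, a] <- w
    Xc <- Xc - tcrossprod(t_sc, P[, a])
    yc <- yc - q[a] * t_sc
    used <- a
  }
  if (used == 0L)
    stop("no usable latent component (X'y is null)", call. = FALSE)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  coefs <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(coefficients = coefs, x_means = x_means, y_mean = y_mean,
                 n_components = used, W = W, P = P, q = q),
            class = "pls_calibrator")
}

#' @rdname pls_calibrator
#' @export
pls_fit <- pls_calibrator

#' @export
#' @method coef pls_calibrator
coef.pls_calibrator <- function(object, ...) object$coefficients

#' @export
#' @method print pls_calibrator
print.pls_calibrator <- function(x, ...) {
  cat(sprintf("<pls_calibrator> %d latent components, %d inputs\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS1 calibrator
#'
#' @param object a [pls_calibrator()].
#' @param newdata matrix (or [intensity_matrix()]) with the model's
#'   columns.
#' @param ... unused.
#' @return predicted contaminant cell counts.
#' @export
#' @method predict pls_calibrator
predict.pls_calibrator <- function(object, newdata, ...) {
  if (inherits(newdata, "intensity_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients), call. = FALSE)
  drop(sweep(newdata, 2L, object$x_means) %*% object$coefficients) +
    object$y_mean
}

#' @rdname predict.pls_calibrator
#' @param model a `pls_calibrator`.
#' @param X new data matrix.
#' @export
pls_predict <- function(model, X) predict(model, X)
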