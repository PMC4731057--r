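#' Principal component analysis of a fingerprint matrix
#'
#' Column-mean-centered singular value decomposition (no unit-variance
#' scaling: fingerprints are already sum-normalized to a common scale).
#' Explained-variance fractions are taken over the full spectrum of
#' singular values so they sum to 1.  Component signs are fixed so that
#' the largest-magnitude loading of each component is positive, making
#' the decomposition reproducible.
#'
#' @param mat an [intensity_matrix()] or plain numeric matrix, >= 2 rows.
#' @param n_components number of components to return (default: full
#'   rank); requests beyond the rank are truncated with a warning.
#' @param center logical, subtract column means (default TRUE).
#' @return an object of class `pca_result`: `scores` (m x c),
#'   `loadings` (n x c), `explained` (fraction per returned component),
#'   `explained_all` (all fractions, summing to 1).
#' @export
pca_decompose <- function(mat, n_components = NULL, center = TRUE) {
  X <- if (inherits(mat, "intensity_matrix")) mat$values else as.matrix(mat)
  m <- nrow(X)
  if (m < 2L) stop("PCA needs at least 2 spectra", call. = FALSE)
  Xc <- if (center) scale(X, center = TRUE, scale = FALSE) else X
  sv <- svd(Xc)
  ev <- sv$d^2
  tot <- sum(ev)
  if (tot == 0) stop("matrix has zero variance", call. = FALSE)
  frac <- ev / tot
  rank <- sum(sv$d > max(sv$d) * max(m, ncol(X)) * .Machine$double.eps)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warning("n_components exceeds the matrix rank (", rank, "); truncated")
    n_components <- rank
  }
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  scores <- Xc %*% loadings
  for (j in k) {                      # sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained = frac[k], explained_all = frac,
                 center = if (center) attr(Xc, "scaled:center") else NULL),
            class = "pca_result")
}

#' @export
#' @method print pca_result
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained: %s\n",
              length(x$explained),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " ")))
  invisible(x)
}

#' Cumulative explained-variance fraction
#'
#' @param result a [pca_decompose()] result.
#' @param k number of leading components (0 returns 0).
#' @return the sum of the first `k` explained-variance fractions.
#' @export
cumulative_variance <- function(result, k) {
  stopifnot(inherits(result, "pca_result"))
  if (k == 0L) return(0)
  if (k > length(result$explained_all))
    stop("k exceeds the number of components", call. = FALSE)
  sum(result$explained_all[seq_len(k)])
}
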