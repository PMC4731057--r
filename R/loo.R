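#' Leave-one-out cross-validation of a calibrator
#'
#' For each spectrum (row) the calibrator is retrained from scratch on
#' the remaining rows -- with a fresh seeded weight initialization for
#' the ANN -- and the left-out row is predicted; predictions are
#' assembled in row order and summarized as a [calibration_result()]
#' (Eq-1 RMS, slope k, R^2, runs test).  This measures the
#' generalization ability of the calibrator to single cases excluded
#' from training.
#'
#' @param X numeric matrix (or [intensity_matrix()] at stage
#'   `"selected"`), >= 3 rows.
#' @param y contaminant cell counts per row.
#' @param method `"ann"` or `"pls"`.
#' @param seed integer; fold f of the ANN uses seed `seed + f`.
#' @param group optional grouping vector (e.g. `sample_id`): when given,
#'   all rows of a group are left out together (mixture-grouped LOO)
#'   instead of single rows.
#' @param ids optional row identifiers for the result table.
#' @param n_hidden,epochs,learning_rate,momentum ANN hyperparameters.
#' @param n_components PLS latent components.
#' @return a [calibration_result()] with the LOO predictions.
#' @export
loo_cross_validate <- function(X, y, method = c("ann", "pls"), seed = 1,
                               group = NULL, ids = NULL, n_hidden = 4,
                               epochs = 3000, learning_rate = 0.01,
                               momentum = 0.9, n_components = 5) {
  method <- match.arg(method)
  if (inherits(X, "intensity_matrix")) {
    if (is.null(ids)) ids <- X$row_ids
    X <- X$values
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  stopifnot(m >= 3L, length(y) == m)
  folds <- if (is.null(group)) as.list(seq_len(m))
           else split(seq_len(m), factor(group, levels = unique(group)))
  pred <- rep(NA_real_, m)
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    keep <- setdiff(seq_len(m), hold)
    fit <- tryCatch({
      if (method == "ann")
        ann_calibrator(X[keep, , drop = FALSE], y[keep], n_hidden = n_hidden,
                       epochs = epochs, learning_rate = learning_rate,
                       momentum = momentum, seed = seed + f)
      else
        pls_calibrator(X[keep, , drop = FALSE], y[keep],
                       n_components = min(n_components, length(keep) - 1L,
                                          ncol(X)))
    }, error = function(e)
      stop(sprintf("fold %d (rows %s) failed: %s", f,
                   paste(hold, collapse = ","), conditionMessage(e)),
           call. = FALSE))
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  calibration_result(y, pred, ids = ids, method = paste0(method, "-loo"))
}

#' Scan hidden-layer sizes by LOO error
#'
#' Trains and cross-validates the network for each candidate hidden-layer
#' size and tabulates the LOO RMS; the minimum is flagged.  This is the
#' architecture-selection step that motivated the default of four hidden
#' neurons.
#'
#' @inheritParams loo_cross_validate
#' @param hidden_range integer vector of candidate hidden sizes.
#' @return data.frame with `n_hidden`, `loo_rms`, `best` (logical,
#'   exactly one TRUE at the argmin).
#' @export
architecture_scan <- function(X, y, hidden_range = 1:8, epochs = 3000,
                              seed = 1, learning_rate = 0.01,
                              momentum = 0.9) {
  stopifnot(length(hidden_range) >= 1L)
  rms <- vapply(hidden_range, function(h) {
    loo_cross_validate(X, y, method = "ann", seed = seed, n_hidden = h,
                       epochs = epochs, learning_rate = learning_rate,
                       momentum = momentum)$rms
  }, numeric(1))
  out <- data.frame(n_hidden = hidden_range, loo_rms = rms,
                    best = FALSE)
  out$best[which.min(out$loo_rms)] <- TRUE
  out
}
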