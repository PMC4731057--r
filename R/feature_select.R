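#' Normalized-SD peak ranking
#'
#' Scores every surviving m/z column by the standard deviation of its
#' intensities across spectra, normalized to the pooled standard
#' deviation of all matrix entries; peaks whose intensity tracks the
#' mixture composition score high, constant peaks score 0.
#'
#' @param mat an [intensity_matrix()] (stage `"thresholded"`), >= 2 rows.
#' @return a data.frame of class `selection_scores` with columns `col`
#'   (column index into `mat`), `mz` and `score`, sorted by descending
#'   score with ties broken by ascending m/z.
#' @export
sd_ranking <- function(mat) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (nrow(mat$values) < 2L)
    stop("sd_ranking needs at least 2 spectra", call. = FALSE)
  total_sd <- stats::sd(as.vector(mat$values))
  if (total_sd == 0)
    stop("matrix has zero total variance", call. = FALSE)
  col_sd <- apply(mat$values, 2L, stats::sd)
  score <- col_sd / total_sd
  out <- data.frame(col = seq_along(score), mz = mat$col_mz, score = score)
  out <- out[order(-out$score, out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("selection_scores", "data.frame")
  out
}

#' Lasso peak selection
#'
#' L1-penalized linear regression of the contaminant cell count on the
#' thresholded fingerprint matrix over a logarithmic penalty path
#' (glmnet); the penalty is chosen by k-fold cross-validated prediction
#' error with the one-standard-error rule, and the columns with nonzero
#' coefficients at that penalty are returned.
#'
#' @param mat an [intensity_matrix()].
#' @param y contaminant cell counts, one per row of `mat`.
#' @param n_lambda length of the penalty path (default 100).
#' @param cv_folds number of CV folds (default 5).
#' @param seed integer seed governing the fold assignment.
#' @return integer vector of selected column indices (possibly empty).
#' @export
lasso_select <- function(mat, y, n_lambda = 100, cv_folds = 5, seed = 1) {
  stopifnot(inherits(mat, "intensity_matrix"))
  y <- as.numeric(y)
  if (length(y) != nrow(mat$values))
    stop("y must have one value per spectrum", call. = FALSE)
  if (stats::var(y) == 0)
    stop("y has zero variance", call. = FALSE)
  if (nrow(mat$values) < cv_folds)
    stop("fewer rows than CV folds", call. = FALSE)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(cv_folds), length(y)))
  cv <- glmnet::cv.glmnet(mat$values, y, alpha = 1, nlambda = n_lambda,
                          foldid = foldid, standardize = TRUE,
                          grouped = length(y) >= 3L * cv_folds)
  b <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1L]  # drop intercept
  which(b != 0)
}

#' Sparse-PLS peak selection
#'
#' Sparse partial least squares for a single response: at each component
#' the weight vector `X'y` is soft-thresholded at the `sparsity` quantile
#' of its absolute loadings, the scores are computed and `X`/`y` are
#' deflated.  Columns with a nonzero loading in any retained component
#' are returned.
#'
#' @param mat an [intensity_matrix()].
#' @param y contaminant cell counts.
#' @param n_components number of latent components (default 2).
#' @param sparsity fraction per component used as the soft-threshold
#'   quantile (0 keeps every column; default 0.8).
#' @param seed integer seed (the algorithm is deterministic; the seed is
#'   recorded for provenance).
#' @return integer vector of selected column indices.
#' @export
spls_select <- function(mat, y, n_components = 2, sparsity = 0.8, seed = 1) {
  stopifnot(inherits(mat, "intensity_matrix"))
  y <- as.numeric(y)
  X <- mat$values
  if (length(y) != nrow(X))
    stop("y must have one value per spectrum", call. = FALSE)
  if (stats::var(y) == 0)
    stop("y has zero variance", call. = FALSE)
  r <- qr(scale(X, center = TRUE, scale = FALSE))$rank
  if (n_components > max(r, 1L))
    stop("n_components must not exceed the rank of the centered matrix",
         call. = FALSE)
  set.seed(seed)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  selected <- integer(0)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    if (all(w == 0)) break
    lam <- if (sparsity <= 0) 0 else stats::quantile(abs(w), sparsity,
                                                     names = FALSE)
    w <- sign(w) * pmax(abs(w) - lam, 0)
    if (all(w == 0)) break
    w <- w / sqrt(sum(w^2))
    t_sc <- drop(Xc %*% w)
    tt <- sum(t_sc^2)
    if (tt < .Machine$double.eps) break
    selected <- union(selected, which(w != 0))
    p <- drop(crossprod(Xc, t_sc)) / tt
    q <- sum(yc * t_sc) / tt
    Xc <- Xc - tcrossprod(t_sc, p)
    yc <- yc - q * t_sc
  }
  sort(selected)
}

#' Combine the three selectors into the final peak panel
#'
#' Each column gets one vote from each method that chose it (the
#' normalized-SD method votes for its top `target_size` columns); columns
#' are ranked by vote count, then SD score, then ascending m/z, and the
#' top `target_size` form the panel.
#'
#' @param sd a [sd_ranking()] result.
#' @param lasso,spls integer index sets from [lasso_select()] /
#'   [spls_select()] (same column space as `sd`).
#' @param target_size panel size (10 and 30 in the two reference series).
#' @return a data.frame of class `peak_panel` with columns `col`, `mz`,
#'   `votes`, `sd_score`, `chosen_by`.
#' @export
combine_panels <- function(sd, lasso, spls, target_size) {
  stopifnot(inherits(sd, "selection_scores"))
  ncols <- nrow(sd)
  if (target_size > ncols)
    stop("target_size exceeds the number of available columns", call. = FALSE)
  sd_set <- sd$col[seq_len(min(target_size, ncols))]
  tab <- data.frame(col = sd$col, mz = sd$mz, sd_score = sd$score)
  in_sd <- tab$col %in% sd_set
  in_la <- tab$col %in% lasso
  in_sp <- tab$col %in% spls
  tab$votes <- in_sd + in_la + in_sp
  tab$chosen_by <- apply(cbind(sd = in_sd, lasso = in_la, spls = in_sp), 1L,
                         function(z) paste(c("sd", "lasso", "spls")[z],
                                           collapse = "+"))
  tab <- tab[order(-tab$votes, -tab$sd_score, tab$mz), ]
  panel <- utils::head(tab, target_size)
  rownames(panel) <- NULL
  class(panel) <- c("peak_panel", "data.frame")
  panel
}

#' Select the informative-peak panel
#'
#' Convenience driver running all three selectors on a thresholded matrix
#' and merging them with [combine_panels()].
#'
#' @param mat an [intensity_matrix()] at stage `"thresholded"`.
#' @param y contaminant cell counts per row.
#' @param target_size panel size.
#' @param seed integer seed for the stochastic selectors.
#' @param cv_folds,n_components,sparsity selector parameters.
#' @return a `peak_panel` (see [combine_panels()]).
#' @export
select_panel <- function(mat, y, target_size, seed = 1, cv_folds = 5,
                         n_components = 2, sparsity = 0.8) {
  sd <- sd_ranking(mat)
  la <- lasso_select(mat, y, cv_folds = cv_folds, seed = seed)
  rk <- qr(scale(mat$values, center = TRUE, scale = FALSE))$rank
  sp <- spls_select(mat, y, n_components = min(n_components, max(rk, 1L)),
                    sparsity = sparsity, seed = seed)
  combine_panels(sd, la, sp, target_size)
}

#' Extract the panel columns from a fingerprint matrix
#'
#' @param mat an [intensity_matrix()] whose columns contain the panel
#'   m/z values.
#' @param panel a `peak_panel`.
#' @return an [intensity_matrix()] at stage `"selected"`, columns in
#'   panel order.
#' @export
apply_panel <- function(mat, panel) {
  stopifnot(inherits(mat, "intensity_matrix"), inherits(panel, "peak_panel"))
  idx <- match(panel$mz, mat$col_mz)
  if (anyNA(idx))
    stop("matrix is missing panel m/z ",
         format(panel$mz[which(is.na(idx))[1L]]), call. = FALSE)
  intensity_matrix(mat$values[, idx, drop = FALSE], row_ids = mat$row_ids,
                   col_mz = panel$mz, stage = "selected")
}
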