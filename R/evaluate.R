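#' Root-mean-square residual
#'
#' The calibration error criterion: for experimental outputs `o_pk` and
#' predicted outputs `o*_pk` over N spectra and M outputs (M = 1 here),
#' `RMS = sqrt( sum_p sum_k (o_pk - o*_pk)^2 / (N * M) )`, in the units
#' of the response (cells).
#'
#' @param experimental,predicted numeric vectors (or N x M matrices) of
#'   equal size.
#' @param M number of outputs per spectrum when vectors are supplied
#'   (default 1).
#' @return the RMS value.
#' @export
rms_eq1 <- function(experimental, predicted, M = 1) {
  e <- as.numeric(experimental)
  p <- as.numeric(predicted)
  if (length(e) == 0L) stop("empty input", call. = FALSE)
  if (length(e) != length(p))
    stop("experimental and predicted differ in length", call. = FALSE)
  if (length(e) %% M != 0L)
    stop("input length is not a multiple of M", call. = FALSE)
  N <- length(e) / M
  sqrt(sum((e - p)^2) / (N * M))
}

#' Regression diagnostics of predicted vs experimental values
#'
#' Ordinary least squares of `predicted = k * experimental + intercept`
#' (free intercept); reports the slope k, the intercept and the
#' determination coefficient R^2 of that fit.  A perfect calibrator gives
#' k = 1, intercept = 0, R^2 = 1.
#'
#' @param experimental,predicted numeric vectors, >= 3 points,
#'   `experimental` not all equal.
#' @return list with `k`, `intercept`, `r2`.
#' @export
regression_diagnostics <- function(experimental, predicted) {
  x <- as.numeric(experimental)
  y <- as.numeric(predicted)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (stats::var(x) == 0)
    stop("experimental values are all equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  list(k = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), r2 = r2)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Operationalizes the visual check that calibration residuals scatter
#' randomly about zero: the residuals (ordered by experimental value)
#' are reduced to their signs, the number of sign runs is compared with
#' its null distribution, and a two-sided normal-approximation p-value is
#' reported.  Small p flags either systematic trend (too few runs) or
#' over-alternation (too many runs).  Zero residuals are dropped.
#'
#' @param residuals numeric, ordered by the experimental value; at least
#'   8 nonzero values.
#' @return list with `runs` (observed run count), `n_pos`, `n_neg`, `z`
#'   and `p_value`.
#' @export
residual_randomness <- function(residuals) {
  r <- as.numeric(residuals)
  r <- r[r != 0]
  if (length(r) < 8L)
    stop("need at least 8 nonzero residuals", call. = FALSE)
  s <- sign(r)
  runs <- 1L + sum(diff(s) != 0)
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 == 0L || n2 == 0L)
    return(list(runs = runs, n_pos = n1, n_neg = n2, z = NA_real_,
                p_value = 0))
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(runs = runs, n_pos = n1, n_neg = n2, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Assemble a calibration result
#'
#' Bundles per-spectrum experimental and predicted contaminant counts
#' with the summary metrics: RMS, regression slope k, R^2 and the
#' residual-randomness runs test.
#'
#' @param experimental,predicted contaminant cell counts per spectrum.
#' @param ids optional row identifiers.
#' @param method label of the calibrator (e.g. `"ann"`, `"pls"`).
#' @return an object of class `calibration_result`: `table` (data.frame
#'   with `id`, `experimental`, `predicted`, `residual`), `n`, `rms`,
#'   `k`, `intercept`, `r2`, `runs_p`, `method`.
#' @export
calibration_result <- function(experimental, predicted, ids = NULL,
                               method = "calibrator") {
  e <- as.numeric(experimental)
  p <- as.numeric(predicted)
  stopifnot(length(e) == length(p), length(e) >= 1L)
  if (is.null(ids)) ids <- as.character(seq_along(e))
  tab <- data.frame(id = ids, experimental = e, predicted = p,
                    residual = e - p, stringsAsFactors = FALSE)
  reg <- if (length(e) >= 3L && stats::var(e) > 0)
    regression_diagnostics(e, p) else list(k = NA_real_,
                                           intercept = NA_real_,
                                           r2 = NA_real_)
  ord <- order(e)
  runs_p <- tryCatch(residual_randomness(tab$residual[ord])$p_value,
                     error = function(err) NA_real_)
  structure(list(table = tab, n = length(e), rms = rms_eq1(e, p),
                 k = reg$k, intercept = reg$intercept, r2 = reg$r2,
                 runs_p = runs_p, method = method),
            class = "calibration_result")
}

#' @export
#' @method print calibration_result
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s: n = %d, RMS = %.4g cells, k = %.4f, R2 = %.4f\n",
              x$method, x$n, x$rms, x$k, x$r2))
  invisible(x)
}

#' @export
#' @method summary calibration_result
summary.calibration_result <- function(object, ...) {
  cat(sprintf("Calibration (%s), %d spectra\n", object$method, object$n))
  cat(sprintf("  RMS        : %.6g cells\n", object$rms))
  cat(sprintf("  slope k    : %.4f\n", object$k))
  cat(sprintf("  intercept  : %.6g cells\n", object$intercept))
  cat(sprintf("  R^2        : %.4f\n", object$r2))
  cat(sprintf("  runs-test p: %.3g\n", object$runs_p))
  invisible(object)
}

#' @export
#' @method residuals calibration_result
residuals.calibration_result <- function(object, ...) {
  object$table$residual
}

#' Predicted-vs-experimental plot of a calibration result
#'
#' @param x a [calibration_result()].
#' @param ... passed to [plot()].
#' @export
#' @method plot calibration_result
plot.calibration_result <- function(x, ...) {
  plot(x$table$experimental, x$table$predicted,
       xlab = "experimental contaminant cells",
       ylab = "predicted contaminant cells",
       main = sprintf("%s: RMS %.3g, k %.3f, R2 %.4f",
                      x$method, x$rms, x$k, x$r2), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(x$intercept, x$k, col = 2)
  invisible(x)
}

#' Write a calibration result to CSV + JSON
#'
#' @param result a [calibration_result()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
write_calibration_result <- function(result, csv_path = NULL,
                                     json_path = NULL) {
  stopifnot(inherits(result, "calibration_result"))
  if (!is.null(csv_path))
    utils::write.csv(result$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(method = result$method, n = result$n,
                              rms = result$rms, k = result$k,
                              intercept = result$intercept, r2 = result$r2,
                              runs_p = result$runs_p),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(result)
}
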