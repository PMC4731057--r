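#' Uniform m/z grid
#'
#' The common grid all spectra are resampled onto before any further
#' processing.  Defaults give 30000 uniformly spaced m/z values across
#' the 2000--20000 range, i.e. a bin width of about 0.6 Da.
#'
#' @param lo,hi m/z range bounds (Da/e).
#' @param n_bins number of grid points (>= 2).
#' @return an object of class `mz_grid`.
#' @export
mz_grid <- function(lo = 2000, hi = 20000, n_bins = 30000) {
  if (!(lo < hi)) stop("mz_grid requires lo < hi", call. = FALSE)
  if (n_bins < 2L) stop("mz_grid requires n_bins >= 2", call. = FALSE)
  structure(list(lo = lo, hi = hi, n_bins = as.integer(n_bins)),
            class = "mz_grid")
}

#' @rdname mz_grid
#' @param grid an `mz_grid`.
#' @return `grid_centers`: the numeric vector of bin centers,
#'   `lo + i * (hi - lo) / (n_bins - 1)` for `i = 0 .. n_bins - 1`.
#' @export
grid_centers <- function(grid) {
  seq(grid$lo, grid$hi, length.out = grid$n_bins)
}

#' Resample a spectrum onto a uniform grid
#'
#' Step (i) of the preprocessing chain: linear interpolation of the raw
#' spectrum at the grid centers.  Input points outside `[lo, hi]` are
#' dropped; grid points outside the support of the input get intensity 0.
#'
#' @param spec a [spectrum()].
#' @param grid an [mz_grid()].
#' @return the resampled [spectrum()] (`stage = "resampled"`), with
#'   exactly `grid$n_bins` points.
#' @export
resample_spectrum <- function(spec, grid = mz_grid()) {
  stopifnot(inherits(spec, "spectrum"), inherits(grid, "mz_grid"))
  if (max(spec$mz) < grid$lo || min(spec$mz) > grid$hi)
    stop("spectrum has no overlap with the grid range", call. = FALSE)
  centers <- grid_centers(grid)
  y <- stats::approx(spec$mz, spec$intensity, xout = centers,
                     method = "linear", rule = 1)$y
  y[is.na(y)] <- 0
  out <- spec
  out$mz <- centers
  out$intensity <- y
  out$stage <- "resampled"
  out
}

shift_intensity <- function(x, d) {
  # shift values by d bins (positive d moves content to higher indices),
  # vacated bins filled with 0
  n <- length(x)
  out <- numeric(n)
  if (d >= 0) out[(1 + d):n] <- x[1:(n - d)]
  else out[1:(n + d)] <- x[(1 - d):n]
  if (abs(d) >= n) out[] <- 0
  out
}

#' Align a set of resampled spectra
#'
#' Step (ii): removes systematic m/z shifts between repeated acquisitions.
#' Each spectrum is shifted by the integer bin offset (at most
#' `max_shift_bins` in magnitude) that maximizes its cross-correlation with
#' the element-wise median reference spectrum of the set; ties favour the
#' smallest |offset|.  Vacated bins are zero-filled.
#'
#' @param spectra list of [spectrum()]s on the same grid.
#' @param max_shift_bins maximum allowed |offset| in bins (default 50,
#'   about 30 Da on the default grid).
#' @param reference optional intensity vector to align against (e.g. the
#'   stored reference of a calibration run when aligning new spectra);
#'   defaults to the element-wise median of the input set.
#' @return list with `spectra` (aligned, `stage = "aligned"`), `offsets`
#'   (applied integer corrections) and `reference`.
#' @export
align_spectra <- function(spectra, max_shift_bins = 50, reference = NULL) {
  stopifnot(length(spectra) >= 1L)
  n <- length(spectra[[1L]]$mz)
  if (max_shift_bins >= n)
    stop("max_shift_bins must be smaller than the grid size", call. = FALSE)
  Y <- vapply(spectra, function(s) {
    if (length(s$mz) != n) stop("spectra are not on a common grid", call. = FALSE)
    s$intensity
  }, numeric(n))
  if (is.null(reference))
    reference <- apply(Y, 1L, stats::median)
  lags <- seq.int(-max_shift_bins, max_shift_bins)
  lags <- lags[order(abs(lags), lags)]        # smallest |d| wins ties
  offsets <- integer(ncol(Y))
  for (k in seq_len(ncol(Y))) {
    x <- Y[, k]
    best <- -Inf; bestd <- 0L
    for (d in lags) {
      if (d >= 0) cc <- sum(x[1:(n - d)] * reference[(1 + d):n])
      else        cc <- sum(x[(1 - d):n] * reference[1:(n + d)])
      if (cc > best) { best <- cc; bestd <- d }
    }
    offsets[k] <- bestd
  }
  out <- vector("list", length(spectra))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    s$intensity <- shift_intensity(s$intensity, offsets[k])
    s$stage <- "aligned"
    out[[k]] <- s
  }
  list(spectra = out, offsets = offsets, reference = reference)
}

#' Subtract a rolling-minimum baseline
#'
#' Step (iii): the baseline is estimated as the rolling minimum over a
#' centered window of `2 * half_window_bins + 1` bins, smoothed by a
#' moving average of the same window, and subtracted; the result is
#' clipped at zero.  The estimate never exceeds the signal, so the output
#' is elementwise <= the input.
#'
#' @param spec a [spectrum()] on a grid.
#' @param half_window_bins window half-width in bins (default 250,
#'   about 150 Da on the default grid).
#' @return the baseline-subtracted [spectrum()] (`stage = "baselined"`).
#' @export
subtract_baseline <- function(spec, half_window_bins = 250) {
  stopifnot(inherits(spec, "spectrum"))
  if (half_window_bins < 1L)
    stop("half_window_bins must be >= 1", call. = FALSE)
  b <- roll_min_cpp(spec$intensity, as.integer(half_window_bins))
  b <- roll_mean_cpp(b, as.integer(half_window_bins))
  out <- spec
  out$intensity <- pmax(spec$intensity - b, 0)
  out$stage <- "baselined"
  out
}

#' Savitzky-Golay smoothing
#'
#' Step (iv): local least-squares polynomial smoothing; reproduces any
#' polynomial of degree <= `polyorder` exactly.  The filter is kept
#' strictly linear -- the slight negative ringing it produces next to
#' sharp peaks (typically < 1% of peak height) is *not* clipped, so the
#' chain remains linear in the input intensities and cannot distort a
#' linear calibration.
#'
#' @param spec a [spectrum()].
#' @param window_bins odd window length in bins (default 21).
#' @param polyorder polynomial order (default 3), must be < `window_bins`.
#' @return the smoothed [spectrum()] (`stage = "smoothed"`).
#' @export
smooth_spectrum <- function(spec, window_bins = 21, polyorder = 3) {
  stopifnot(inherits(spec, "spectrum"))
  if (window_bins %% 2L != 1L)
    stop("window_bins must be odd", call. = FALSE)
  if (polyorder >= window_bins)
    stop("polyorder must be smaller than window_bins", call. = FALSE)
  out <- spec
  out$intensity <- as.numeric(signal::sgolayfilt(spec$intensity,
                                                 p = polyorder,
                                                 n = window_bins))
  out$stage <- "smoothed"
  out
}

#' Normalize a spectrum to unit sum
#'
#' Step (v): divides the intensities by their sum so that the fingerprint
#' satisfies sum(X_i) = 1 (an L1 normalization; `mode = "l2"` gives unit
#' Euclidean length instead).
#'
#' @param spec a [spectrum()].
#' @param mode `"sum"` (default) or `"l2"`.
#' @return the normalized [spectrum()] (`stage = "normalized"`).
#' @export
normalize_spectrum <- function(spec, mode = c("sum", "l2")) {
  stopifnot(inherits(spec, "spectrum"))
  mode <- match.arg(mode)
  s <- if (mode == "sum") sum(spec$intensity) else sqrt(sum(spec$intensity^2))
  if (!is.finite(s) || s <= 0)
    stop("cannot normalize an all-zero spectrum", call. = FALSE)
  out <- spec
  out$intensity <- spec$intensity / s
  out$stage <- "normalized"
  out
}

#' Assemble normalized spectra into the fingerprint matrix
#'
#' Rows follow the manifest order (the i-th row is the fingerprint of the
#' i-th mixture); columns are the grid centers.  Each spectrum is matched
#' to its manifest row by (`sample_id`, `replicate`).
#'
#' @param spectra list of normalized [spectrum()]s on a common grid.
#' @param manifest a [read_manifest()] manifest.
#' @return an [intensity_matrix()] at stage `"normalized"`.
#' @export
build_matrix <- function(spectra, manifest) {
  stopifnot(length(spectra) >= 1L)
  keys <- vapply(spectra, function(s) paste(s$sample_id, s$replicate), "")
  if (anyDuplicated(keys))
    stop("duplicate (sample_id, replicate) among spectra", call. = FALSE)
  want <- paste(manifest$sample_id, manifest$replicate)
  idx <- match(want, keys)
  if (anyNA(idx))
    stop("no spectrum for manifest entry ", want[which(is.na(idx))[1L]],
         call. = FALSE)
  mz0 <- spectra[[idx[1L]]]$mz
  rows <- lapply(idx, function(i) {
    s <- spectra[[i]]
    if (length(s$mz) != length(mz0) || any(s$mz != mz0))
      stop("spectra are not on a common grid", call. = FALSE)
    if (s$stage != "normalized")
      stop("all spectra must be normalized before matrix assembly",
           call. = FALSE)
    s$intensity
  })
  intensity_matrix(do.call(rbind, rows), row_ids = want, col_mz = mz0,
                   stage = "normalized")
}

#' Intensity-threshold peak filter
#'
#' Keeps the m/z columns whose maximum over all spectra is strictly
#' greater than the threshold (default 1e-3 on sum-normalized
#' fingerprints), discarding bins that never rise above the latent noise.
#'
#' @param mat an [intensity_matrix()] at stage `"normalized"` (or already
#'   `"thresholded"`, in which case the filter is idempotent).
#' @param threshold intensity threshold (strict comparison).
#' @return the filtered [intensity_matrix()] at stage `"thresholded"`.
#' @export
threshold_filter <- function(mat, threshold = 1e-3) {
  stopifnot(inherits(mat, "intensity_matrix"))
  keep <- apply(mat$values, 2L, max) > threshold
  if (!any(keep))
    stop("no m/z column exceeds the intensity threshold", call. = FALSE)
  intensity_matrix(mat$values[, keep, drop = FALSE], row_ids = mat$row_ids,
                   col_mz = mat$col_mz[keep], stage = "thresholded")
}

#' Run the five-step preprocessing chain
#'
#' Applies, in order: resampling onto the common grid, alignment against
#' the median reference, rolling-minimum baseline subtraction,
#' Savitzky-Golay smoothing and sum-to-one normalization, then assembles
#' the fingerprint matrix in manifest order.
#'
#' @param spectra list of raw [spectrum()]s.
#' @param manifest a [read_manifest()] manifest.
#' @param grid an [mz_grid()].
#' @param max_shift_bins,half_window_bins,window_bins,polyorder,normalize_mode
#'   chain parameters, see the individual steps.
#' @param reference optional alignment reference (intensity vector on the
#'   grid), used when preprocessing new spectra against a stored run.
#' @return list with `matrix` (an [intensity_matrix()], stage
#'   `"normalized"`), `offsets` and `reference`.
#' @export
preprocess_spectra <- function(spectra, manifest, grid = mz_grid(),
                               max_shift_bins = 50, half_window_bins = 250,
                               window_bins = 21, polyorder = 3,
                               normalize_mode = "sum", reference = NULL) {
  res <- lapply(spectra, resample_spectrum, grid = grid)
  al <- align_spectra(res, max_shift_bins = max_shift_bins,
                      reference = reference)
  done <- lapply(al$spectra, function(s) {
    s <- subtract_baseline(s, half_window_bins = half_window_bins)
    s <- smooth_spectrum(s, window_bins = window_bins, polyorder = polyorder)
    normalize_spectrum(s, mode = normalize_mode)
  })
  list(matrix = build_matrix(done, manifest),
       offsets = al$offsets, reference = al$reference)
}
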