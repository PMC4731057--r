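test_that("resampling interpolates onto the grid centers", {
  g <- mz_grid(2000, 2100, 101)                  # 1 Da bins
  s <- grid_spectrum(g, runif(101))
  r <- resample_spectrum(s, g)
  expect_equal(r$intensity, s$intensity)         # identity on-grid
  expect_equal(length(r), g$n_bins)
  expect_equal(r$stage, "resampled")

  # triangle through (center - delta, 0), (midpoint, 10), (center + delta, 0)
  # with delta = bin width: the two flanking centers interpolate to 5
  mid <- 2050.5
  tri <- spectrum(c(2000, mid - 1, mid, mid + 1, 2100), c(0, 0, 10, 0, 0))
  rt <- resample_spectrum(tri, g)
  expect_equal(rt$intensity[rt$mz == 2050], 5)
  expect_equal(rt$intensity[rt$mz == 2051], 5)

  expect_equal(mz_grid()$n_bins, 30000L)
  expect_length(grid_centers(mz_grid()), 30000L)

  off <- spectrum(c(5000, 6000), c(1, 1))
  expect_error(resample_spectrum(off, mz_grid(2000, 4000, 100)), "overlap")
})

test_that("alignment recovers integer shifts against the median reference", {
  g <- mz_grid(2000, 4000, 2001)
  base <- exp(-(grid_centers(g) - 3000)^2 / 50) +
    0.5 * exp(-(grid_centers(g) - 2400)^2 / 30)
  sp <- lapply(1:4, function(i) grid_spectrum(g, base, sample_id = paste0("s", i)))

  al0 <- align_spectra(sp, max_shift_bins = 20)
  expect_equal(al0$offsets, rep(0L, 4))          # identical spectra

  shifted <- sp
  shifted[[2]]$intensity <- c(rep(0, 3), base[1:(length(base) - 3)])  # +3 bins
  al <- align_spectra(shifted, max_shift_bins = 20)
  expect_equal(al$offsets[2], -3L)
  expect_equal(al$spectra[[2]]$intensity[10:1990], base[10:1990],
               tolerance = 1e-12)

  al2 <- align_spectra(al$spectra, max_shift_bins = 20)   # idempotent
  expect_equal(al2$offsets, rep(0L, 4))

  expect_error(align_spectra(sp, max_shift_bins = 3000), "smaller")
})

test_that("baseline subtraction removes flat and ramp backgrounds", {
  g <- mz_grid(2000, 4000, 2001)
  flat <- grid_spectrum(g, rep(3.7, 2001))
  b <- subtract_baseline(flat, half_window_bins = 50)
  expect_equal(b$intensity, rep(0, 2001))
  expect_equal(b$stage, "baselined")

  ctr <- grid_centers(g)
  peak <- exp(-(ctr - 3000)^2 / (2 * 3^2)) * 8    # sigma 3 Da, height 8
  p <- subtract_baseline(grid_spectrum(g, peak), half_window_bins = 100)
  expect_gt(max(p$intensity), 8 * 0.95)           # height kept within 5%
  expect_true(all(p$intensity <= peak + 1e-12))   # output <= input

  ramp <- (ctr - 2000) / 2000 * 5
  r <- subtract_baseline(grid_spectrum(g, peak + ramp), half_window_bins = 100)
  resid_ramp <- r$intensity[abs(ctr - 3000) > 50]
  expect_lt(max(resid_ramp), 0.1 * 5)             # ramp reduced by > 90%

  expect_error(subtract_baseline(flat, half_window_bins = 0), ">= 1")
})

test_that("Savitzky-Golay smoothing reproduces polynomials, damps noise", {
  g <- mz_grid(2000, 2200, 201)
  x <- seq_len(201)
  quad <- 5 + 0.3 * x + 0.01 * x^2
  s <- smooth_spectrum(grid_spectrum(g, quad), window_bins = 21, polyorder = 3)
  expect_equal(s$intensity, quad, tolerance = 1e-9)
  expect_equal(s$stage, "smoothed")

  const <- smooth_spectrum(grid_spectrum(g, rep(4, 201)))
  expect_equal(const$intensity, rep(4, 201))

  set.seed(21)
  noisy <- rnorm(201, mean = 50, sd = 1)          # positive-mean white noise
  sm <- smooth_spectrum(grid_spectrum(g, noisy))
  expect_lt(var(sm$intensity), var(noisy))

  expect_error(smooth_spectrum(grid_spectrum(g, quad), window_bins = 20),
               "odd")
  expect_error(smooth_spectrum(grid_spectrum(g, quad), window_bins = 5,
                               polyorder = 7), "smaller")
})

test_that("normalization gives unit sum and is a fixed point", {
  s <- spectrum(c(2000, 3000), c(1, 3))
  n <- normalize_spectrum(s)
  expect_equal(n$intensity, c(0.25, 0.75))
  expect_equal(n$stage, "normalized")

  n2 <- normalize_spectrum(n)
  expect_equal(n2$intensity, n$intensity)         # idempotent

  set.seed(5)
  r <- normalize_spectrum(spectrum(sort(runif(50, 2000, 9000)), runif(50)))
  expect_equal(sum(r$intensity), 1, tolerance = 1e-12)

  l2 <- normalize_spectrum(s, mode = "l2")
  expect_equal(sqrt(sum(l2$intensity^2)), 1, tolerance = 1e-12)

  expect_error(normalize_spectrum(spectrum(c(2000, 3000), c(0, 0))),
               "all-zero")
})

test_that("matrix assembly follows manifest order and checks linkage", {
  g <- mz_grid(2000, 2010, 11)
  mk <- function(id, rep, v) normalize_spectrum(
    grid_spectrum(g, rep(v, 11), sample_id = id, replicate = rep))
  sp <- list(mk("a", 1, 1), mk("b", 1, 2), mk("a", 2, 3))
  man <- validate_manifest(data.frame(
    sample_id = c("b", "a", "a"), file = NA, n_cells_A = 1,
    n_cells_B = 0, replicate = c(1L, 2L, 1L)))
  m <- build_matrix(sp, man)
  expect_equal(m$row_ids, c("b 1", "a 2", "a 1"))
  m2 <- build_matrix(rev(sp), man)                # input order irrelevant
  expect_equal(m2$values, m$values)

  expect_error(build_matrix(sp[1:2], man), "no spectrum")
  bad <- c(sp[1:2], list(normalize_spectrum(grid_spectrum(
    mz_grid(2000, 2010, 12), rep(1, 12), sample_id = "a", replicate = 2))))
  expect_error(build_matrix(bad, man), "common grid")
})

test_that("threshold filter keeps columns by strict column maximum", {
  m <- intensity_matrix(rbind(c(0.0005, 0.002, 0.0),
                              c(0.0009, 0.0, 0.9)),
                        c("r1", "r2"), c(2100, 2200, 2300),
                        stage = "normalized")
  t1 <- threshold_filter(m, 1e-3)
  expect_equal(t1$col_mz, c(2200, 2300))
  expect_equal(t1$stage, "thresholded")

  t0 <- threshold_filter(m, 0)
  expect_equal(ncol(t0$values), 3L)               # any positive value kept

  # brute-force oracle on random matrices; idempotence; subset property
  set.seed(7)
  for (i in 1:20) {
    mm <- random_intensity_matrix(sample(2:8, 1), sample(3:12, 1),
                                  stage = "normalized")
    thr <- runif(1, 0, 2)
    keep <- logical(ncol(mm$values))
    for (j in seq_along(keep)) keep[j] <- max(mm$values[, j]) > thr
    if (!any(keep)) {
      expect_error(threshold_filter(mm, thr), "threshold")
    } else {
      got <- threshold_filter(mm, thr)
      expect_equal(got$col_mz, mm$col_mz[keep])
      expect_true(all(got$col_mz %in% mm$col_mz))
      again <- threshold_filter(got, thr)
      expect_equal(again$values, got$values)
    }
  }
})

test_that("the full chain preserves rows, unit sums and planted fingerprints", {
  ds <- small_default_dataset()
  pipe <- small_default_pipeline()
  M <- pipe$pp$matrix
  expect_equal(nrow(M$values), length(ds$spectra))
  expect_lt(max(abs(rowSums(M$values) - 1)), 1e-9)

  # noiseless variant on the default grid: chain output matches the
  # directly rendered fingerprint up to normalization (cosine similarity)
  cfg <- ds$config
  cfg$jitter_sd <- 0; cfg$mult_cv <- 0; cfg$additive_sd <- 0
  cfg$baseline_amp <- 0
  cfg$replicates <- 1L
  cfg$designs <- cfg$designs[c(1, 6, 12), ]
  nds <- make_calibration_dataset(cfg)
  npp <- preprocess_spectra(nds$spectra, nds$manifest)
  for (i in 1:3) {
    truth <- resample_spectrum(nds$spectra[[i]], mz_grid())$intensity
    row <- npp$matrix$values[i, ]
    cosim <- sum(truth * row) / sqrt(sum(truth^2) * sum(row^2))
    expect_gte(cosim, 0.999)
  }
})
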