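test_that("normalized-SD ranking matches a two-pass oracle and its invariances", {
  m <- intensity_matrix(cbind(rep(0.5, 4), c(1, 2, 3, 4), rep(0.1, 4)),
                        paste0("r", 1:4), c(2100, 2200, 2300),
                        stage = "thresholded")
  sc <- sd_ranking(m)
  expect_equal(sc$score[sc$mz == 2100], 0)       # constant column
  expect_equal(sc$mz[1], 2200)                    # only varying column first

  set.seed(31)
  for (i in 1:10) {
    mm <- random_intensity_matrix(10, 8)
    sc <- sd_ranking(mm)
    pooled <- sqrt(sum((mm$values - mean(mm$values))^2) /
                     (length(mm$values) - 1))
    for (j in 1:8) {
      v <- mm$values[, j]
      oracle <- sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / pooled
      expect_equal(sc$score[sc$col == j], oracle, tolerance = 1e-12)
    }
    # invariance: row permutation, positive scaling
    perm <- mm; perm$values <- mm$values[sample(10), ]
    expect_equal(sd_ranking(perm)$score, sd_ranking(mm)$score)
    scl <- mm; scl$values <- mm$values * 3.7
    expect_equal(sd_ranking(scl)$score, sd_ranking(mm)$score,
                 tolerance = 1e-12)
  }
  one <- random_intensity_matrix(1, 4)
  expect_error(sd_ranking(one), "at least 2")
})

test_that("lasso selects planted columns and rejects pure noise", {
  set.seed(1)
  n <- 40; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- 5 * X[, 7]                                  # exactly proportional
  m <- intensity_matrix(X, paste0("r", 1:n), 2000 + (1:p) * 10,
                        stage = "thresholded")
  sel <- lasso_select(m, y, seed = 1)
  expect_true(7 %in% sel)

  for (s in 1:10) {                                # null: y independent
    set.seed(100 + s)
    y0 <- rnorm(n)
    sel0 <- lasso_select(m, y0, seed = s)
    expect_lte(length(sel0), 2L)
  }

  X2 <- cbind(X, X[, 7])                           # duplicated informative col
  m2 <- intensity_matrix(X2, paste0("r", 1:n), 2000 + (1:(p + 1)) * 10,
                         stage = "thresholded")
  sel2 <- lasso_select(m2, y, seed = 1)
  expect_true(any(c(7, p + 1) %in% sel2))

  expect_error(lasso_select(m, rep(1, n)), "zero variance")
})

test_that("sparse PLS selects planted columns; sparsity 0 keeps all", {
  set.seed(2)
  n <- 40; p <- 10
  X <- matrix(rnorm(n * p, sd = 0.05), n, p)
  X[, 4] <- seq(0, 1, length.out = n)              # strong planted column
  y <- 3 * X[, 4]
  m <- intensity_matrix(X, paste0("r", 1:n), 2000 + (1:p) * 10,
                        stage = "thresholded")
  sel <- spls_select(m, y, n_components = 2, sparsity = 0.9, seed = 1)
  expect_true(4 %in% sel)
  expect_lt(length(sel), p)

  all_sel <- spls_select(m, y, n_components = 1, sparsity = 0, seed = 1)
  expect_equal(all_sel, 1:p)

  sets <- lapply(1:5, function(s)
    spls_select(m, y, n_components = 2, sparsity = 0.9, seed = s))
  for (s in 2:5) expect_equal(sets[[s]], sets[[1]])  # deterministic

  expect_error(spls_select(m, y, n_components = 50), "rank")
  expect_error(spls_select(m, rep(0, n)), "zero variance")
})

test_that("panel combination ranks by votes, SD score, then m/z", {
  set.seed(3)
  m <- random_intensity_matrix(12, 84)
  sc <- sd_ranking(m)
  # pick a low-SD column endorsed by both selectors vs one endorsed by one
  low2 <- sc$col[(nrow(sc) - 1):nrow(sc)]
  pan <- combine_panels(sc, lasso = low2, spls = low2[1], target_size = 10)
  expect_equal(nrow(pan), 10L)
  r_both <- which(pan$col == low2[1])
  r_one <- which(pan$col == low2[2])
  expect_true(length(r_both) == 1L)
  expect_true(length(r_one) == 0L || r_both < r_one)

  pan0 <- combine_panels(sc, integer(0), integer(0), target_size = 10)
  expect_equal(pan0$col, sc$col[1:10])             # degenerate: SD top-10
  expect_error(combine_panels(sc, integer(0), integer(0), 200), "exceeds")
})

test_that("the combined panel recovers planted composition-tracking peaks", {
  # acceptance-style recovery: q = 8 planted peaks, SNR >= 10, 10 seeds
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 40; p <- 60; q <- 8
    frac <- runif(n)
    X <- matrix(rnorm(n * p, sd = 0.01), n, p)
    planted <- sample(p, q)
    for (j in planted)
      X[, j] <- X[, j] + frac * runif(1, 0.1, 0.3) * sample(c(-1, 1), 1)
    y <- frac * 1e6
    m <- intensity_matrix(abs(X), paste0("r", 1:n), 2000 + (1:p) * 25,
                          stage = "thresholded")
    pan <- select_panel(m, y, target_size = 10, seed = s)
    hits <- hits + length(intersect(pan$col, planted))
    total <- total + q
  }
  expect_gte(hits / total, 0.9)
})

test_that("panel size is exactly min(target, available) and applies cleanly", {
  set.seed(8)
  m <- random_intensity_matrix(10, 20)
  y <- rnorm(10)
  pan <- select_panel(m, y, target_size = 7, seed = 1)
  expect_equal(nrow(pan), 7L)
  X <- apply_panel(m, pan)
  expect_equal(X$stage, "selected")
  expect_equal(X$col_mz, pan$mz)
  bad <- m; bad$col_mz <- bad$col_mz + 1
  expect_error(apply_panel(bad, pan), "missing panel m/z")
})
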