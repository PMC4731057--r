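test_that("PLS1 is exact on noiseless linear data", {
  set.seed(41)
  X <- matrix(rnorm(100), 20, 5)
  b <- c(2, -1, 0.5, 3, -2)
  y <- drop(X %*% b) + 7
  fit <- pls_calibrator(X, y, n_components = 5)
  expect_equal(predict(fit, X), y, tolerance = 1e-6)
})

test_that("one-component PLS on rank-1 X matches OLS on the latent score", {
  set.seed(42)
  t_sc <- rnorm(15)
  X <- outer(t_sc, c(1, 2, -1))
  y <- 4 * t_sc + 2
  fit <- pls_calibrator(X, y, n_components = 1)
  ols <- lm(y ~ t_sc)
  expect_equal(predict(fit, X), unname(fitted(ols)), tolerance = 1e-9)
})

test_that("PLS coefficients agree with an independent reference fit", {
  skip_if_not_installed("mixOmics")
  set.seed(43)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rnorm(12)
  for (A in 1:3) {
    fit <- pls_calibrator(X, y, n_components = A)
    ref <- mixOmics::pls(X, y, ncomp = A, scale = FALSE, mode = "regression")
    Xnew <- matrix(rnorm(25), 5, 5, dimnames = list(NULL, paste0("v", 1:5)))
    mine <- predict(fit, Xnew)
    theirs <- drop(predict(ref, Xnew)$predict[, 1, A])
    expect_equal(mine, unname(theirs), tolerance = 1e-6)
  }
})

test_that("PLS guards degenerate inputs", {
  X <- matrix(1, 10, 3)
  expect_error(pls_calibrator(X, rnorm(10), n_components = 1), "variance|null")
  expect_error(pls_calibrator(matrix(rnorm(20), 10, 2), rnorm(10),
                              n_components = 5), "n_components")
  fit <- pls_calibrator(matrix(rnorm(30), 10, 3), rnorm(10), 2)
  expect_error(predict(fit, matrix(0, 2, 5)), "columns")
})

test_that("network initialization is seeded and correctly shaped", {
  m1 <- ann_init(10, 4, seed = 5)
  m2 <- ann_init(10, 4, seed = 5)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$w2, m2$w2)
  expect_equal(dim(m1$W1), c(10L, 4L))
  expect_length(m1$w2, 4L)
  expect_length(m1$b1, 4L)
  expect_equal(m1$b1, rep(0, 4))
  expect_equal(m1$b2, 0)
  expect_true(all(abs(m1$W1) <= 0.5))
  m3 <- ann_init(10, 4, seed = 6)
  expect_false(identical(m1$W1, m3$W1))
})

test_that("untrained zero network predicts the response midpoint", {
  m <- ann_init(3, 4, seed = 1)
  m$W1[] <- 0; m$w2[] <- 0
  m$scaling <- list(x_min = rep(0, 3), x_rng = rep(1, 3),
                    y_min = 2e5, y_rng = 6e5)
  pred <- ann_predict(m, matrix(runif(12), 4, 3))
  expect_equal(pred, rep(2e5 + 0.5 * 6e5, 4))     # sigmoid(0) = 0.5
})

test_that("training fits constants, lines and single patterns", {
  set.seed(44)
  Xc <- matrix(runif(30), 30, 1)
  mc <- ann_calibrator(Xc, rep(5e5, 30), epochs = 1000, seed = 1)
  expect_equal(unname(predict(mc, Xc)), rep(5e5, 30), tolerance = 0.01)

  set.seed(9)
  X <- matrix(runif(30), 30, 1)
  y <- drop(2e5 + 6e5 * X)
  ml <- ann_calibrator(X, y, epochs = 150000, trace_every = 1, seed = 3)
  tr <- ml$trace$train_rms
  expect_true(all(diff(tr[1:100]) <= 0))          # early descent is monotone
  expect_lt(tr[length(tr)], 0.01 * diff(range(y)))

  m1 <- ann_calibrator(matrix(0.5), 3e5, epochs = 4000, seed = 1)
  expect_lt(abs(predict(m1, matrix(0.5)) - 3e5), 1)   # memorization
})

test_that("training and prediction are exactly reproducible", {
  set.seed(45)
  X <- matrix(runif(60), 20, 3)
  y <- rowSums(X) * 1e5
  a <- ann_calibrator(X, y, epochs = 500, seed = 9)
  b <- ann_calibrator(X, y, epochs = 500, seed = 9)
  expect_identical(a$W1, b$W1)
  expect_identical(predict(a, X), predict(a, X))
  expect_error(ann_predict(a, matrix(0, 2, 5)), "columns")
})

test_that("leave-one-out equals a hand-rolled fold loop on m = 3", {
  set.seed(46)
  X <- matrix(runif(6), 3, 2)
  y <- c(1e5, 4e5, 8e5)

  # PLS route
  loo <- loo_cross_validate(X, y, method = "pls", n_components = 1)
  hand <- numeric(3)
  for (p in 1:3) {
    fit <- pls_calibrator(X[-p, , drop = FALSE], y[-p], n_components = 1)
    hand[p] <- predict(fit, X[p, , drop = FALSE])
  }
  expect_equal(loo$table$predicted, hand, tolerance = 1e-12)
  expect_equal(loo$rms, rms_eq1(y, hand), tolerance = 1e-12)

  # ANN route with fresh seeded init per fold
  looa <- loo_cross_validate(X, y, method = "ann", epochs = 200, seed = 7)
  handa <- numeric(3)
  for (p in 1:3) {
    fit <- ann_calibrator(X[-p, , drop = FALSE], y[-p], epochs = 200,
                          seed = 7 + p)
    handa[p] <- predict(fit, X[p, , drop = FALSE])
  }
  expect_equal(looa$table$predicted, handa, tolerance = 1e-12)
})

test_that("LOO of an uninformative network reproduces the mean-out value", {
  set.seed(47)
  X <- matrix(1, 12, 2)                            # constant inputs
  y <- rnorm(12, 5e5, 1e5)
  loo <- loo_cross_validate(X, y, method = "ann", epochs = 3000, seed = 1)
  hand_pred <- vapply(1:12, function(p) mean(y[-p]), 1)
  expect_equal(loo$rms, rms_eq1(y, hand_pred), tolerance = 0.05)
})

test_that("row permutation permutes deterministic LOO predictions", {
  set.seed(48)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10, 5e5, 2e5)
  loo <- loo_cross_validate(X, y, method = "pls", n_components = 2)
  o <- sample(10)
  loo2 <- loo_cross_validate(X[o, ], y[o], method = "pls", n_components = 2)
  expect_equal(loo2$table$predicted, loo$table$predicted[o], tolerance = 1e-9)
})

test_that("mixture-grouped LOO leaves whole replicate groups out", {
  set.seed(49)
  X <- matrix(rnorm(24), 12, 2)
  y <- rep(c(1e5, 3e5, 5e5, 8e5), each = 3)
  grp <- rep(letters[1:4], each = 3)
  loo <- loo_cross_validate(X, y, method = "pls", n_components = 2,
                            group = grp)
  hand <- numeric(12)
  for (g in letters[1:4]) {
    hold <- which(grp == g)
    fit <- pls_calibrator(X[-hold, ], y[-hold], n_components = 2)
    hand[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  expect_equal(loo$table$predicted, hand, tolerance = 1e-12)
})

test_that("architecture scan tabulates one LOO RMS per candidate", {
  set.seed(50)
  X <- matrix(runif(30), 15, 2)
  y <- drop(1e5 + 8e5 * X[, 1])
  tab <- architecture_scan(X, y, hidden_range = c(1, 2, 4), epochs = 8000,
                           seed = 2)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$n_hidden, c(1, 2, 4))
  expect_equal(which(tab$best), which.min(tab$loo_rms))
  # noiseless linear problem: 1 hidden neuron already near the best
  expect_lt(tab$loo_rms[1], 2 * min(tab$loo_rms))
})

test_that("long training does not overfit the verification split", {
  pipe <- mef28_pipeline()
  n <- nrow(pipe$X$values)
  set.seed(51)
  hold <- sample(n, 30)
  fit <- ann_calibrator(pipe$X$values[-hold, ], pipe$y[-hold],
                        epochs = 100000, trace_every = 100,
                        verification = list(X = pipe$X$values[hold, ],
                                            y = pipe$y[hold]),
                        seed = 4)
  v <- fit$trace$verif_rms
  run_min <- cummin(v)
  expect_lt(max(v / run_min), 1.10)
})

test_that("ANN models round-trip through JSON", {
  set.seed(52)
  X <- matrix(runif(40), 10, 4)
  y <- rowSums(X) * 2e5
  fit <- ann_calibrator(X, y, epochs = 500, seed = 3)
  f <- tempfile(fileext = ".json")
  write_ann_model(fit, f)
  back <- read_ann_model(f)
  expect_equal(ann_predict(back, X), unname(predict(fit, X)),
               tolerance = 1e-12)
})
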