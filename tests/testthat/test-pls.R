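test_that("one informative column is fit exactly by one component", {
  set.seed(1)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- 2 + 3 * X[, 4]
  fit1 <- fit_pls1(X[, 4, drop = FALSE], y, rank = 1)
  expect_equal(fit1$fitted, y, tolerance = 1e-10)
  expect_equal(r_squared(y, fit1$fitted), 1, tolerance = 1e-10)
})

test_that("the first PLS weight vector is proportional to X'y after centering", {
  set.seed(2)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  fit <- fit_pls1(X, y, rank = 3)
  Xc <- scale(X, scale = FALSE)
  w_ref <- crossprod(Xc, y - mean(y))[, 1]
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(fit$W[, 1], w_ref, tolerance = 1e-12)
})

test_that("full-rank PLS equals the normal-equations OLS solution", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 25; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n, sd = 2)
    fit <- fit_pls1(X, y, rank = p)
    Xc <- scale(X, scale = FALSE)
    beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))[, 1]
    expect_equal(fit$coef, beta, tolerance = 1e-8,
                 info = paste("seed", seed))
  }
})

test_that("training RMSEC is non-increasing in rank", {
  set.seed(5)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- X %*% rnorm(12) + rnorm(40)
  fit <- fit_pls1(X, y, rank = 10)
  rmsec <- vapply(1:10, function(a) rmse(y, predict(fit, X, rank = a)), 0)
  expect_true(all(diff(rmsec) <= 1e-12))
})

test_that("deflation shrinks the X'y residual covariance monotonically", {
  set.seed(6)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- X %*% rnorm(10) + rnorm(30)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  norms <- numeric(5)
  Xd <- Xc; yd <- yc
  fit <- fit_pls1(X, y, rank = 5)
  for (a in 1:5) {
    norms[a] <- sqrt(sum(crossprod(Xd, yd)^2))
    t <- Xd %*% fit$W[, a]
    Xd <- Xd - t %*% t(fit$P[, a])
    yd <- yd - fit$q[a] * t
  }
  expect_true(all(diff(norms) < 0))
})

test_that("fit_pls1 validates rank, variance and missing values", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls1(X, rep(1, 10), 1), "zero variance")
  expect_error(fit_pls1(X, rnorm(10), 3), "rank")
  expect_error(fit_pls1(X, c(NA, rnorm(9)), 1), "missing")
})

test_that("LOO cross-validation holds out every sample exactly once", {
  set.seed(7)
  X <- matrix(rnorm(5 * 3), 5, 3)
  y <- rnorm(5)
  cv <- cross_validate(X, y, max_rank = 2, scheme = "LOO")
  expect_length(cv$predictions, 5)
  expect_false(anyNA(cv$predictions))
  # held-out prediction differs from a training-set prediction
  fit <- fit_pls1(X, y, 2)
  expect_false(isTRUE(all.equal(cv$predictions, fit$fitted)))
  expect_error(cross_validate(X, y, max_rank = 4), "max_rank")
})

test_that("pure-noise responses keep RMSECV near sd(y) and ranks small", {
  ratios <- matrix(NA_real_, 50, 4)
  chosen <- integer(50)
  for (seed in 1:50) {
    set.seed(seed + 100)
    X <- matrix(rnorm(24 * 10), 24, 10)
    y <- rnorm(24)
    cv <- cross_validate(X, y, max_rank = 4, scheme = "LOO")
    ratios[seed, ] <- cv$rmsecv / sd(y)
    chosen[seed] <- cv$rank
  }
  expect_true(all(colMeans(ratios) >= 0.95))
  expect_lte(median(chosen), 2)
})

test_that("grid search ranks candidates by RMSECV and survives failures", {
  r <- random_spectra(30, 40, seed = 12)
  y <- r$absorbance[, 10] + rnorm(30, 0, 0.05)
  one <- grid_search(r, y, list(pretreatment_spec()), max_rank = 3)
  direct <- cross_validate(r$absorbance, y, 3)
  expect_equal(one$rmsecv, min(direct$rmsecv))
  expect_equal(one$rank, direct$rank)
  # a degenerate candidate (SNV on a constant-row set) is recorded, not fatal
  s <- spectra_set(rbind(rep(1, 40), matrix(rnorm(40 * 9), 9, 40)),
                   r$wavenumbers)
  y2 <- rnorm(10)
  g <- grid_search(s, y2, list(pretreatment_spec("SNV"), pretreatment_spec()),
                   max_rank = 2)
  expect_equal(sum(g$ok), 1)
  expect_match(g$error[!g$ok], "degenerate")
})

test_that("calibration models predict their training set and persist to JSON", {
  cfg <- tiny_cfg(seed = 31)
  sim <- simulate_nirs(cfg)
  spec <- pretreatment_spec("SNV", windows = list(c(4247, 6102)))
  y <- sim$reference$CP
  m <- fit_calibration(sim$spectra, y, spec, rank = 5, parameter = "CP")
  yhat <- predict(m, sim$spectra)
  expect_equal(unname(yhat), m$fit$fitted, tolerance = 1e-10)
  f <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, f)
  m2 <- read_pls_model(f)
  expect_equal(unname(predict(m2, sim$spectra)), unname(yhat),
               tolerance = 1e-12)
  expect_equal(m2$spec$steps, m$spec$steps)
  expect_equal(m2$fit$rank, m$fit$rank)
})

test_that("MSC-bearing models ignore constant offsets in new spectra", {
  cfg <- tiny_cfg(seed = 32)
  sim <- simulate_nirs(cfg)
  m <- fit_calibration(sim$spectra, sim$reference$CP,
                       pretreatment_spec("MSC"), rank = 4, parameter = "CP")
  shifted <- spectra_set(sim$spectra$absorbance + 0.25,
                         sim$spectra$wavenumbers, sim$spectra$sample_ids)
  expect_equal(unname(predict(m, shifted)), unname(predict(m, sim$spectra)),
               tolerance = 1e-6)
})

test_that("prediction is invariant to sample order and checks the grid", {
  cfg <- tiny_cfg(seed = 33)
  sim <- simulate_nirs(cfg)
  m <- fit_calibration(sim$spectra, sim$reference$CP,
                       pretreatment_spec("SNV"), rank = 3, parameter = "CP")
  perm <- rev(sim$spectra$sample_ids)
  expect_equal(predict(m, sim$spectra[perm, ]),
               predict(m, sim$spectra)[perm])
  truncated <- sim$spectra[, sim$spectra$wavenumbers < 5000]
  expect_error(predict(m, truncated), "grid")
})
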