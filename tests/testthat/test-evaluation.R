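test_that("rmse matches an explicit loop oracle and validates input", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
  set.seed(3)
  y <- rnorm(50); yhat <- rnorm(50)
  acc <- 0
  for (i in 1:50) acc <- acc + (y[i] - yhat[i])^2
  expect_equal(rmse(y, yhat), sqrt(acc / 50), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "mismatch")
})

test_that("r_squared is 1-SSE/SST and equals squared Pearson for affine fits", {
  y <- c(2, 4, 6, 8, 11)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  yhat <- 0.5 + 0.9 * y
  # affine predictions: both definitions coincide only after regression;
  # check against the algebraic identity instead
  expect_equal(r_squared(y, yhat),
               1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  expect_error(r_squared(rep(1, 3), 1:3), "constant")
})

test_that("published NDF/ADF/WSC ratio cells are reproduced at 2 dp", {
  # calibration-side: RPD = SD/RMSECV, RER = range/RMSECV, PRL = RMSECV/SEL
  expect_equal(round(rpd(9.48, 2.23), 2), 4.25)
  expect_equal(round(rer(21.29, 60.47, 2.23), 2), 17.57)
  expect_equal(round(prl(2.23, 1.62), 2), 1.38)
  expect_equal(round(rpd(6.12, 1.68), 2), 3.64)
  expect_equal(round(prl(1.68, 1.43), 2), 1.17)
  # validation-side
  expect_equal(round(rpd(8.95, 2.60), 2), 3.44)
  expect_equal(round(rer(24.14, 55.41, 2.60), 2), 12.03)
  expect_equal(round(rer(13.23, 33.88, 1.32), 2), 15.64)
  expect_equal(round(prl(2.56, 1.64), 2), 1.56)
  expect_equal(round(rpd(1, 1), 2), 1)
  expect_equal(round(rer(1, 2, 1), 2), 1)
})

test_that("SEL is the pooled within-sample replicate sd", {
  same <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                     value = rep(c(5, 7), each = 3))
  expect_equal(sel(same), 0)
  one_pair <- data.frame(sample_id = c("a", "a"), value = c(1, 3))
  expect_equal(sel(one_pair), sqrt(2))
  expect_error(sel(data.frame(sample_id = c("a", "a", "b"),
                              value = c(1, 2, 3))), ">= 2 replicates")
  # simulation oracle: triplicates with known within-sample sd
  set.seed(9)
  n <- 200; sigma <- 1.5
  reps <- data.frame(sample_id = rep(sprintf("S%03d", 1:n), each = 3),
                     value = rep(runif(n, 10, 40), each = 3) +
                       rnorm(3 * n, 0, sigma))
  expect_lt(abs(sel(reps) - sigma) / sigma, 0.10)
})

test_that("ratio identities hold to 1e-12 on random inputs", {
  set.seed(77)
  for (i in 1:200) {
    sdv <- runif(1, 0.5, 12)
    e <- runif(1, 0.1, 5)
    lo <- runif(1, 0, 30); hi <- lo + runif(1, 1, 40)
    sl <- runif(1, 0.2, 3)
    expect_equal(rpd(sdv, e) * e, sdv, tolerance = 1e-12)
    expect_equal(rer(lo, hi, e) * e, hi - lo, tolerance = 1e-12)
    expect_equal(prl(e, sl) * sl, e, tolerance = 1e-12)
    expect_equal(rer(lo, hi, e), rpd(sdv, e) * (hi - lo) / sdv,
                 tolerance = 1e-12)
  }
})

test_that("quality banding follows the screening guideline scale", {
  expect_equal(quality_band(0.99, 9.4), "excellent")
  expect_equal(quality_band(0.92, 3.4), "successful")
  expect_equal(quality_band(0.5, 1.2), "inadequate")
  expect_equal(quality_band(0.85, 2.5), "intermediate")
})

test_that("eval_report rows satisfy the statistic identities", {
  set.seed(15)
  y <- runif(30, 10, 50)
  yhat <- y + rnorm(30, 0, 2)
  reps <- data.frame(sample_id = rep(paste0("S", 1:30), each = 2),
                     CP = rep(y, each = 2) + rnorm(60, 0, 1))
  r <- eval_report("CP", y, yhat, role = "P", replicates = reps, rank = 5L)
  expect_equal(r$rpd * r$rmse, r$sd, tolerance = 1e-12)
  expect_equal(r$rer * r$rmse, r$max - r$min, tolerance = 1e-12)
  expect_equal(r$prl * r$sel, r$rmse, tolerance = 1e-12)
  expect_false(r$overflow)
  # statistics are invariant to sample order
  perm <- sample(30)
  r2 <- eval_report("CP", y[perm], yhat[perm], role = "P",
                    replicates = reps, rank = 5L)
  expect_equal(r2[c("r2", "rmse", "rpd", "rer", "sel", "prl")],
               r[c("r2", "rmse", "rpd", "rer", "sel", "prl")])
  # perfect predictions flag the ratio overflow instead of erroring
  rp <- eval_report("CP", y, y, role = "C")
  expect_true(rp$overflow)
  expect_equal(rp$r2, 1)
  expect_true(is.infinite(rp$rpd))
  # rendering rounds to 2 dp without touching stored precision
  tab <- render_report(list(r, rp))
  expect_equal(tab$rmse[1], round(r$rmse, 2))
})
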