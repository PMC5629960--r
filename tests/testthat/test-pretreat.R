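test_that("SNV standardizes every spectrum (n-1 sd) and rejects constants", {
  s <- spectra_set(matrix(c(1, 2, 3), 1), c(4000, 4010, 4020))
  expect_equal(snv(s)$absorbance[1, ], c(-1, 0, 1))
  expect_error(snv(spectra_set(matrix(5, 1, 3), 1:3)), "degenerate")
  r <- random_spectra(5, 20, seed = 2)
  out <- snv(r)$absorbance
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_equal(unname(apply(out, 1, sd)), rep(1, 5))
})

test_that("SNV and MMN are invariant to positive per-row affine transforms", {
  s <- random_spectra(4, 30, seed = 5)
  a <- c(0.1, -0.2, 0.3, 0); b <- c(2, 0.5, 1.7, 3)
  s2 <- spectra_set(a + b * s$absorbance, s$wavenumbers, s$sample_ids)
  expect_equal(snv(s2)$absorbance, snv(s)$absorbance, tolerance = 1e-12)
  expect_equal(mmn(s2)$absorbance, mmn(s)$absorbance, tolerance = 1e-12)
})

test_that("MSC inverts per-row affine scatter against its reference", {
  wn <- seq(4000, 5000, length.out = 80)
  parent <- 0.4 + 0.3 * exp(-((wn - 4500) / 120)^2)
  set.seed(11)
  a <- rnorm(6, 0, 0.1); b <- rnorm(6, 1, 0.2)
  A <- a + b %o% parent
  s <- spectra_set(A, wn)
  # reference = parent spectrum: exact inversion
  out <- msc(s, ref = parent)$spectra$absorbance
  expect_lt(max(abs(sweep(out, 2, parent))), 1e-8)
  # calibration mode (mean reference): all rows collapse to one spectrum
  out2 <- msc(s)$spectra$absorbance
  expect_lt(max(apply(out2, 2, function(col) diff(range(col)))), 1e-8)
  # identity and pure-affine cases
  one <- spectra_set(matrix(parent, 1), wn)
  expect_equal(msc(one, ref = parent)$spectra$absorbance[1, ], parent)
  two <- spectra_set(matrix(2 * parent + 3, 1), wn)
  expect_equal(msc(two, ref = parent)$spectra$absorbance[1, ], parent)
})

test_that("MMN maps each row onto [0, 1] and is idempotent", {
  s <- spectra_set(matrix(c(2, 4, 6), 1), 1:3)
  expect_equal(mmn(s)$absorbance[1, ], c(0, 0.5, 1))
  r <- random_spectra(6, 25, seed = 8)
  out <- mmn(r)
  expect_equal(unname(apply(out$absorbance, 1, min)), rep(0, 6))
  expect_equal(unname(apply(out$absorbance, 1, max)), rep(1, 6))
  expect_equal(mmn(out)$absorbance, out$absorbance)
})

test_that("Savitzky-Golay derivatives are exact on low-order polynomials", {
  p <- 60
  j <- seq_len(p)
  lin <- spectra_set(matrix(3 * j, 1), j)
  d1 <- savgol_derivative(lin, order = 1, window = 17, poly = 2)
  interior <- 9:(p - 8)
  expect_equal(d1$absorbance[1, interior], rep(3, length(interior)),
               tolerance = 1e-10)
  quad <- spectra_set(matrix(0.5 * j^2 - 2 * j, 1), j)
  d2 <- savgol_derivative(quad, order = 2, window = 11, poly = 2)
  expect_equal(d2$absorbance[1, interior], rep(1, length(interior)),
               tolerance = 1e-8)
  expect_error(savgol_derivative(lin, window = 16), "odd")
  expect_error(savgol_derivative(lin, window = 101), "exceeds")
  expect_error(savgol_derivative(lin, order = 1, window = 7, poly = 0),
               "window > poly >= order")
})

test_that("Savitzky-Golay first derivative tracks a dense analytic oracle", {
  p <- 300
  j <- seq_len(p)
  x <- sin(2 * pi * j / 150)
  s <- spectra_set(matrix(x, 1), j)
  d <- savgol_derivative(s, order = 1, window = 17, poly = 2)$absorbance[1, ]
  # oracle: central differences on a 10x upsampled analytic curve,
  # evaluated back on the original index grid
  jf <- seq(1, p, by = 0.1)
  xf <- sin(2 * pi * jf / 150)
  df <- (xf[3:length(xf)] - xf[1:(length(xf) - 2)]) / (2 * 0.1)
  oracle <- approx(jf[2:(length(jf) - 1)], df, xout = j)$y
  interior <- 9:(p - 8)
  rms_rel <- sqrt(mean((d[interior] - oracle[interior])^2)) /
    sqrt(mean(oracle[interior]^2))
  expect_lt(rms_rel, 0.02)
})

test_that("SLS removes straight lines, leaves zero-mean residuals, idempotent", {
  wn <- seq(4000, 5000, length.out = 40)
  lin <- spectra_set(matrix(0.2 + 0.001 * wn, 1), wn)
  expect_lt(max(abs(sls(lin)$absorbance)), 1e-10)
  par <- spectra_set(matrix((wn - 4500)^2 / 1e5, 1), wn)
  out <- sls(par)
  expect_lt(abs(mean(out$absorbance)), 1e-10)
  # explicit OLS oracle: residuals of lm fit
  fit <- lm(par$absorbance[1, ] ~ wn)
  expect_equal(out$absorbance[1, ], unname(resid(fit)), tolerance = 1e-8)
  expect_equal(sls(out)$absorbance, out$absorbance, tolerance = 1e-12)
})

test_that("COE zeroes the row minimum and is idempotent", {
  s <- spectra_set(matrix(c(3, 4, 5), 1), 1:3)
  expect_equal(coe(s)$absorbance[1, ], c(0, 1, 2))
  r <- random_spectra(5, 12, seed = 4)
  out <- coe(r)
  expect_equal(unname(apply(out$absorbance, 1, min)), rep(0, 5))
  expect_equal(coe(out)$absorbance, out$absorbance)
})

test_that("pretreatments act per row: permuting samples permutes outputs", {
  r <- random_spectra(6, 30, seed = 13)
  perm <- c(4, 1, 6, 2, 5, 3)
  rp <- r[perm, ]
  for (f in list(snv, mmn, sls, coe,
                 function(x) savgol_derivative(x, 1, 11, 2))) {
    expect_equal(f(rp)$absorbance, f(r)$absorbance[perm, ],
                 ignore_attr = TRUE)
  }
})

test_that("window restriction keeps exactly the points inside the intervals", {
  wn <- seq(4000, 12500, length.out = 300)
  s <- spectra_set(matrix(rnorm(300), 1), wn)
  out <- restrict_windows(s, list(c(4247, 4602), c(5446, 6102)))
  expect_true(all((out$wavenumbers >= 4247 & out$wavenumbers <= 4602) |
                  (out$wavenumbers >= 5446 & out$wavenumbers <= 6102)))
  expect_false(any(out$wavenumbers > 4602 & out$wavenumbers < 5446))
  expect_error(restrict_windows(s, list(c(1000, 2000))), "no spectral points")
})

test_that("apply_pretreatment composes steps in order, windows last", {
  r <- random_spectra(8, 120, seed = 21, wn = seq(4000, 6500, length.out = 120))
  spec <- pretreatment_spec(c("FD", "MSC"), windows = list(c(4247, 6102)))
  out <- apply_pretreatment(r, spec)
  manual <- msc(savgol_derivative(r, 1, 17, 2))
  expect_equal(out$spectra$absorbance,
               restrict_windows(manual$spectra,
                                list(c(4247, 6102)))$absorbance)
  expect_equal(out$ref, manual$ref)
  # empty step list with a window = column subset only
  sub <- apply_pretreatment(r, pretreatment_spec(windows = list(c(4247, 6102))))
  expect_equal(sub$spectra$absorbance,
               restrict_windows(r, list(c(4247, 6102)))$absorbance)
  expect_null(sub$ref)
})

test_that("SNV does not commute with window restriction (order is fixed)", {
  r <- random_spectra(4, 60, seed = 30)
  w <- list(c(4200, 4600))
  after <- restrict_windows(snv(r), w)$absorbance
  before <- snv(restrict_windows(r, w))$absorbance
  expect_gt(max(abs(after - before)), 1e-6)
})

test_that("pretreatment specs validate their closed name set and windows", {
  expect_error(pretreatment_spec("OSC"), "unknown")
  expect_error(pretreatment_spec("SNV", windows = list(c(5000, 4000))),
               "lo < hi")
  expect_error(pretreatment_spec("FD", window = 8), "odd")
})
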