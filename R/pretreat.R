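#' Standard normal variate (SNV)
#'
#' Per-spectrum standardization: each row is centered by its own mean and
#' scaled by its own standard deviation (n-1 denominator), removing per-sample
#' additive offsets and multiplicative scatter.
#'
#' @param s a [spectra_set].
#' @return A [spectra_set] whose rows all have mean 0 and sd 1.
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  A <- s$absorbance
  mu <- rowMeans(A)
  sdev <- apply(A, 1, stats::sd)
  if (any(sdev == 0))
    stop("degenerate (constant) spectrum, cannot apply SNV: ",
         paste(s$sample_ids[sdev == 0], collapse = ", "))
  spectra_set((A - mu) / sdev, s$wavenumbers, s$sample_ids)
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares, x ~ a + b * ref, and corrected to (x - a) / b.  In calibration
#' mode (`ref = NULL`) the reference is the mean spectrum of `s` and is
#' returned so that new samples can be corrected against the calibration
#' reference at prediction time.
#'
#' @param s a [spectra_set].
#' @param ref numeric vector: the scatter reference spectrum, or `NULL` to
#'   estimate it as `colMeans(s$absorbance)`.
#' @return list with elements `spectra` (corrected [spectra_set]) and `ref`
#'   (the reference used).
#' @export
msc <- function(s, ref = NULL) {
  stopifnot(inherits(s, "spectra_set"))
  A <- s$absorbance
  if (is.null(ref)) ref <- colMeans(A)
  if (length(ref) != ncol(A))
    stop("scatter reference length does not match spectral grid")
  rc <- ref - mean(ref)
  den <- sum(rc^2)
  if (den == 0) stop("scatter reference is constant; MSC undefined")
  # OLS slope: sum(rc) == 0, so b = <x, rc> / <rc, rc>
  b <- as.vector(A %*% rc) / den
  a <- rowMeans(A) - b * mean(ref)
  if (any(b == 0))
    stop("degenerate spectrum (zero fitted scatter slope): ",
         paste(s$sample_ids[b == 0], collapse = ", "))
  corrected <- (A - a) / b
  list(spectra = spectra_set(corrected, s$wavenumbers, s$sample_ids),
       ref = as.numeric(ref))
}

#' Min-max normalization (MMN)
#'
#' Each spectrum is mapped linearly so that its minimum becomes 0 and its
#' maximum becomes 1.
#'
#' @param s a [spectra_set].
#' @return A [spectra_set] with per-row range exactly [0, 1].
#' @export
mmn <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  A <- s$absorbance
  lo <- apply(A, 1, min)
  hi <- apply(A, 1, max)
  if (any(hi == lo))
    stop("degenerate (constant) spectrum, cannot min-max normalize: ",
         paste(s$sample_ids[hi == lo], collapse = ", "))
  spectra_set((A - lo) / (hi - lo), s$wavenumbers, s$sample_ids)
}

#' Savitzky-Golay derivative (first or second)
#'
#' Smoothed derivative per spectrum, computed by local polynomial fitting
#' over a moving window.  The derivative is taken per unit of wavenumber
#' index (grid step), not per cm^-1.  Edges are handled by the fitted
#' polynomial so the output length equals the input length.
#'
#' @param s a [spectra_set].
#' @param order derivative order, 1 (FD) or 2 (SED).
#' @param window odd window length in points (default 17).
#' @param poly polynomial order (default 2); must satisfy
#'   `window > poly >= order`.
#' @return A [spectra_set] of derivative spectra.
#' @export
savgol_derivative <- function(s, order = 1, window = 17, poly = 2) {
  stopifnot(inherits(s, "spectra_set"))
  if (!order %in% c(1, 2)) stop("derivative order must be 1 or 2")
  if (window %% 2 != 1 || window < 5) stop("window must be odd and >= 5")
  if (!(window > poly && poly >= order))
    stop("need window > poly >= order")
  if (ncol(s$absorbance) < window)
    stop("window (", window, ") exceeds number of spectral points (",
         ncol(s$absorbance), ")")
  A <- t(apply(s$absorbance, 1, function(x)
    signal::sgolayfilt(x, p = poly, n = window, m = order, ts = 1)))
  spectra_set(A, s$wavenumbers, s$sample_ids)
}

#' Straight line subtraction (SLS, detrend)
#'
#' Subtracts from each spectrum its own least-squares straight line over the
#' wavenumber axis, removing linear baseline drift.  The output has zero OLS
#' slope and zero mean per row; the operation is idempotent.
#'
#' @param s a [spectra_set].
#' @return A detrended [spectra_set].
#' @export
sls <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (ncol(s$absorbance) < 2) stop("need at least 2 spectral points")
  x <- s$wavenumbers
  xc <- x - mean(x)
  den <- sum(xc^2)
  A <- s$absorbance
  slope <- as.vector(A %*% xc) / den
  fitted <- rowMeans(A) + outer(slope, xc)
  spectra_set(A - fitted, s$wavenumbers, s$sample_ids)
}

#' Constant offset elimination (COE)
#'
#' Subtracts each spectrum's minimum so every row's minimum is exactly 0.
#'
#' @param s a [spectra_set].
#' @return A [spectra_set] with per-row minimum 0.
#' @export
coe <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  A <- s$absorbance
  spectra_set(A - apply(A, 1, min), s$wavenumbers, s$sample_ids)
}

#' Pretreatment specification
#'
#' An ordered list of pretreatment steps plus optional wavenumber windows.
#' Step names come from the closed set SNV, MSC, MMN, FD, SED, SLS, COE.
#' FD/SED carry Savitzky-Golay `window` (odd, >= 5) and `poly` parameters.
#' Windows are `[lo, hi]` intervals in cm^-1, applied after all steps.
#'
#' @param steps character vector of step names, in application order, e.g.
#'   `c("FD", "MSC")`; may be empty for raw spectra.
#' @param windows list of length-2 numeric vectors, or NULL for the full grid.
#' @param window,poly Savitzky-Golay parameters used by FD/SED steps.
#' @return A `pretreatment_spec` object.
#' @export
pretreatment_spec <- function(steps = character(), windows = NULL,
                              window = 17, poly = 2) {
  steps <- as.character(steps)
  allowed <- c("SNV", "MSC", "MMN", "FD", "SED", "SLS", "COE")
  bad <- setdiff(steps, allowed)
  if (length(bad)) stop("unknown pretreatment step(s): ",
                        paste(bad, collapse = ", "))
  if (window %% 2 != 1 || window < 5) stop("window must be odd and >= 5")
  if (!is.null(windows)) {
    windows <- lapply(windows, as.numeric)
    for (w in windows) {
      if (length(w) != 2 || !(w[1] < w[2]))
        stop("each window must be [lo, hi] with lo < hi")
    }
  }
  structure(list(steps = steps, windows = windows,
                 sg_window = window, sg_poly = poly),
            class = "pretreatment_spec")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat("<pretreatment_spec> steps: ",
      if (length(x$steps)) paste(x$steps, collapse = " + ") else "(raw)",
      sep = "")
  if (!is.null(x$windows))
    cat("; windows: ",
        paste(vapply(x$windows, function(w)
          paste0("[", w[1], ", ", w[2], "]"), ""), collapse = " U "),
        " cm-1", sep = "")
  cat("\n")
  invisible(x)
}

#' Restrict a spectra set to wavenumber windows
#'
#' Keeps the columns whose wavenumbers fall inside the union of the given
#' closed intervals.
#'
#' @param s a [spectra_set].
#' @param windows list of `[lo, hi]` intervals (cm^-1).
#' @return The column-restricted [spectra_set].
#' @export
restrict_windows <- function(s, windows) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.null(windows) || length(windows) == 0) return(s)
  keep <- Reduce(`|`, lapply(windows, function(w)
    s$wavenumbers >= w[1] & s$wavenumbers <= w[2]))
  if (!any(keep)) stop("window restriction leaves no spectral points")
  s[, keep]
}

#' Apply a pretreatment specification
#'
#' Applies the steps in listed order on the full grid, then restricts the
#' result to the spec's wavenumber windows.  Applying windows after the
#' per-row transforms avoids derivative edge artifacts at window boundaries
#' and makes the chain order-deterministic.  The MSC scatter reference is
#' estimated from `s` when `ref` is `NULL` (calibration mode) and reused
#' otherwise (prediction mode).
#'
#' @param s a [spectra_set].
#' @param spec a [pretreatment_spec].
#' @param ref scatter reference for MSC, or NULL to estimate.
#' @return list with `spectra` (pretreated, window-restricted [spectra_set])
#'   and `ref` (the MSC scatter reference used, or NULL if no MSC step).
#' @export
apply_pretreatment <- function(s, spec, ref = NULL) {
  stopifnot(inherits(s, "spectra_set"), inherits(spec, "pretreatment_spec"))
  used_ref <- NULL
  for (st in spec$steps) {
    s <- switch(st,
      SNV = snv(s),
      MMN = mmn(s),
      SLS = sls(s),
      COE = coe(s),
      FD  = savgol_derivative(s, 1, spec$sg_window, spec$sg_poly),
      SED = savgol_derivative(s, 2, spec$sg_window, max(spec$sg_poly, 2)),
      MSC = {
        m <- msc(s, ref)
        used_ref <- m$ref
        m$spectra
      })
  }
  list(spectra = restrict_windows(s, spec$windows), ref = used_ref)
}
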