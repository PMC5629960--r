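#' Fit a full NIRS calibration model
#'
#' Bundles a pretreatment chain, its MSC scatter reference, the working
#' wavenumber window and a PLS1 fit into a self-contained model that can be
#' applied to raw spectra.  Pretreatment runs on the model's full grid; the
#' window restriction is applied afterwards; PLS is fit on the restricted
#' matrix.
#'
#' @param s calibration [spectra_set] (raw, full grid).
#' @param y reference values (%DM) aligned with `s$sample_ids`.
#' @param spec a [pretreatment_spec].
#' @param rank number of PLS components.
#' @param parameter constituent name (for reporting), e.g. `"CP"`.
#' @return A `pls_model`: the `pls_fit` plus provenance (`spec`,
#'   `scatter_ref`, `grid_wavenumbers`, working `wavenumbers`, `parameter`,
#'   training-response range `y_range`).
#' @export
fit_calibration <- function(s, y, spec, rank, parameter = "y") {
  stopifnot(inherits(s, "spectra_set"), inherits(spec, "pretreatment_spec"))
  pre <- apply_pretreatment(s, spec)
  fit <- fit_pls1(pre$spectra$absorbance, y, rank)
  structure(list(fit = fit, spec = spec, scatter_ref = pre$ref,
                 grid_wavenumbers = s$wavenumbers,
                 wavenumbers = pre$spectra$wavenumbers,
                 parameter = parameter,
                 y_range = range(y)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$parameter, ": ",
      if (length(x$spec$steps)) paste(x$spec$steps, collapse = "+") else "raw",
      ", rank ", x$fit$rank, ", ", length(x$wavenumbers),
      " working points\n", sep = "")
  invisible(x)
}

# Align a spectra_set onto a target wavenumber grid: exact match (within
# tol) selects columns; otherwise linear interpolation, provided the new
# grid covers the target range.
align_grid <- function(s, target, tol = 1e-6) {
  idx <- match(TRUE, abs(s$wavenumbers[1] - target[1]) <= tol)
  if (length(s$wavenumbers) == length(target) &&
      all(abs(s$wavenumbers - target) <= tol))
    return(s)
  if (min(s$wavenumbers) > min(target) + tol ||
      max(s$wavenumbers) < max(target) - tol)
    stop("wavenumber grid mismatch: input grid [",
         min(s$wavenumbers), ", ", max(s$wavenumbers),
         "] does not cover the model grid [",
         min(target), ", ", max(target), "]")
  A <- t(apply(s$absorbance, 1, function(row)
    stats::approx(s$wavenumbers, row, xout = target)$y))
  spectra_set(A, target, s$sample_ids)
}

#' Predict constituent values from raw spectra
#'
#' Applies the model's own pretreatment (reusing its calibration scatter
#' reference), window restriction and PLS coefficients.  Spectra on a
#' different but covering grid are linearly interpolated onto the model
#' grid.
#'
#' @param object a `pls_model`.
#' @param newdata a [spectra_set] of raw spectra.
#' @param ... unused.
#' @return Named numeric vector of predictions (%DM), one per sample.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectra_set"))
  s <- align_grid(newdata, object$grid_wavenumbers)
  pre <- apply_pretreatment(s, object$spec, ref = object$scatter_ref)
  yhat <- predict(object$fit, pre$spectra$absorbance)
  names(yhat) <- s$sample_ids
  yhat
}

#' Persist a calibration model as JSON
#'
#' Writes pretreatment provenance, windows, rank, centering vectors and
#' regression coefficients with full double precision, so predictions are
#' reproducible bit-for-bit across sessions.
#'
#' @param m a `pls_model`.
#' @param path output JSON path.
#' @export
write_pls_model <- function(m, path) {
  stopifnot(inherits(m, "pls_model"))
  doc <- list(
    parameter = m$parameter,
    steps = as.list(m$spec$steps),
    windows_lo = vapply(m$spec$windows, `[`, 0, 1),
    windows_hi = vapply(m$spec$windows, `[`, 0, 2),
    sg_window = m$spec$sg_window,
    sg_poly = m$spec$sg_poly,
    rank = m$fit$rank,
    grid_wavenumbers = m$grid_wavenumbers,
    wavenumbers = m$wavenumbers,
    scatter_ref = m$scatter_ref,
    x_mean = m$fit$x_mean,
    x_scale = m$fit$x_scale,
    y_mean = m$fit$y_mean,
    W = as.numeric(m$fit$W), P = as.numeric(m$fit$P), q = m$fit$q,
    coef = m$fit$coef, intercept = m$fit$intercept,
    y_range = m$y_range)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read back a persisted calibration model
#'
#' @param path JSON path written by [write_pls_model].
#' @return A `pls_model`.
#' @export
read_pls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  windows <- if (length(doc$windows_lo) == 0) NULL else
    Map(c, as.numeric(doc$windows_lo), as.numeric(doc$windows_hi))
  spec <- pretreatment_spec(steps = doc$steps, windows = windows,
                            window = doc$sg_window, poly = doc$sg_poly)
  p <- length(doc$coef)
  fit <- structure(list(
    x_mean = as.numeric(doc$x_mean),
    x_scale = as.numeric(doc$x_scale),
    y_mean = doc$y_mean,
    W = matrix(as.numeric(doc$W), p), P = matrix(as.numeric(doc$P), p),
    q = as.numeric(doc$q), rank = doc$rank,
    coef = as.numeric(doc$coef), intercept = doc$intercept),
    class = "pls_fit")
  structure(list(fit = fit, spec = spec,
                 scatter_ref = if (is.null(doc$scatter_ref)) NULL else
                   as.numeric(doc$scatter_ref),
                 grid_wavenumbers = as.numeric(doc$grid_wavenumbers),
                 wavenumbers = as.numeric(doc$wavenumbers),
                 parameter = doc$parameter,
                 y_range = as.numeric(doc$y_range)),
            class = "pls_model")
}
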