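#' Root mean square error
#'
#' @param y reference values; @param yhat predictions, same length.
#' @return `sqrt(mean((y - yhat)^2))`, in the units of `y` (%DM here).
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch: y vs yhat")
  if (length(y) < 1) stop("need at least one observation")
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST`, with SST about the mean of `y`.  This is the
#' cross-validation / external-validation R2 of calibration reporting, not
#' the squared Pearson correlation (they coincide when predictions are an
#' affine map of y).
#'
#' @param y reference values; @param yhat predictions.
#' @return Dimensionless R2 (can be negative for models worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch: y vs yhat")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant reference values: R2 undefined")
  1 - sum((y - yhat)^2) / sst
}

#' Ratio of prediction to deviation (RPD)
#'
#' SD of the reference values divided by the model RMSE (RMSECV for
#' calibration, RMSEP for external validation).  Guideline: > 3 successful,
#' > 4 excellent for screening.
#'
#' @param sd standard deviation of the reference values (%DM).
#' @param rmse model error (%DM).
#' @return Dimensionless ratio `sd / rmse`.
#' @export
rpd <- function(sd, rmse) {
  if (sd <= 0 || rmse <= 0) stop("rpd needs sd > 0 and rmse > 0")
  sd / rmse
}

#' Range error ratio (RER)
#'
#' Reference-value range divided by the model RMSE; values above 10 indicate
#' high screening utility.
#'
#' @param ymin,ymax reference minimum and maximum (%DM).
#' @param rmse model error (%DM).
#' @return Dimensionless ratio `(ymax - ymin) / rmse`.
#' @export
rer <- function(ymin, ymax, rmse) {
  if (!(ymax > ymin)) stop("rer needs ymax > ymin")
  if (rmse <= 0) stop("rer needs rmse > 0")
  (ymax - ymin) / rmse
}

#' Standard error of laboratory (SEL)
#'
#' Pooled within-sample standard deviation of replicate laboratory
#' measurements: `sqrt( sum_i sum_j (y_ij - ybar_i)^2 / sum_i (r_i - 1) )`.
#' Estimates the precision of the reference wet-chemistry method.
#'
#' @param replicates data.frame with columns `sample_id` and `value`, or a
#'   replicate-resolved `reference_table` plus `parameter` naming the column.
#' @param parameter column to use when `replicates` has several.
#' @return SEL in %DM.
#' @export
sel <- function(replicates, parameter = "value") {
  df <- as.data.frame(replicates)
  if (!parameter %in% names(df))
    stop("no column '", parameter, "' in replicate table")
  v <- split(df[[parameter]], df$sample_id)
  r <- lengths(v)
  if (any(r < 2))
    stop("every sample needs >= 2 replicates for SEL; offending: ",
         paste(names(v)[r < 2], collapse = ", "))
  ss <- sum(vapply(v, function(x) sum((x - mean(x))^2), 0))
  sqrt(ss / sum(r - 1))
}

#' Prediction error relative to laboratory (PRL)
#'
#' Model RMSE scaled by laboratory precision; values below 2 mean the model
#' predicts within twice the wet-chemistry replicate error.
#'
#' @param rmse model error (%DM); @param sel laboratory error (%DM).
#' @return Dimensionless ratio `rmse / sel`.
#' @export
prl <- function(rmse, sel) {
  if (sel <= 0) stop("prl needs sel > 0")
  rmse / sel
}

#' Guideline quality band for a validated calibration
#'
#' Screening-guideline classification: excellent if R2 > 0.95 and RPD > 4;
#' successful if R2 in 0.9-0.95 and RPD in 3-4 (boundaries inclusive
#' upward); inadequate if R2 < 0.7 and RPD < 1.75; otherwise intermediate.
#'
#' @param r2 validation R2; @param rpd validation RPD.
#' @return One of `"excellent"`, `"successful"`, `"intermediate"`,
#'   `"inadequate"`.
#' @export
quality_band <- function(r2, rpd) {
  if (r2 > 0.95 && rpd > 4) "excellent"
  else if (r2 >= 0.9 && rpd >= 3) "successful"
  else if (r2 < 0.7 && rpd < 1.75) "inadequate"
  else "intermediate"
}

#' Assemble one evaluation-report row
#'
#' Computes the full statistic bundle for one set of reference values and
#' predictions: n, mean/sd/min/max of the references, R2, RMSE (of the role
#' given), RPD, RER, and — when a replicate table is supplied — SEL and PRL.
#' Ratios are carried at full precision; use [render_report] for the 2-dp
#' table view.  A perfect fit (rmse == 0) is flagged via `overflow = TRUE`
#' and infinite ratios.
#'
#' @param parameter constituent name.
#' @param y reference values (%DM); @param yhat predictions.
#' @param role which error this is: `"C"` (calibration), `"CV"` or `"P"`.
#' @param replicates optional replicate table for SEL (see [sel]).
#' @param rank optional model rank, carried through for reporting.
#' @return An `eval_report` (named list / one table row).
#' @export
eval_report <- function(parameter, y, yhat, role = c("CV", "C", "P"),
                        replicates = NULL, rank = NA_integer_) {
  role <- match.arg(role)
  e <- rmse(y, yhat)
  sdy <- stats::sd(y)
  overflow <- e == 0
  selv <- if (!is.null(replicates)) sel(replicates, parameter) else NA_real_
  out <- list(parameter = parameter, role = role, n = length(y),
              mean = mean(y), sd = sdy, min = min(y), max = max(y),
              r2 = r_squared(y, yhat), rmse = e,
              rpd = if (overflow) Inf else rpd(sdy, e),
              rer = if (overflow) Inf else rer(min(y), max(y), e),
              sel = selv,
              prl = if (is.na(selv)) NA_real_ else prl(e, selv),
              rank = rank, overflow = overflow)
  out$band <- quality_band(out$r2, out$rpd)
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (RMSE%s): n=%d R2=%.2f RMSE=%.2f RPD=%.2f RER=%.2f%s [%s]\n",
              x$parameter, x$role, x$n, x$r2, x$rmse, x$rpd, x$rer,
              if (!is.na(x$sel)) sprintf(" SEL=%.2f PRL=%.2f", x$sel, x$prl) else "",
              x$band))
  invisible(x)
}

#' Render evaluation reports as a 2-dp table
#'
#' @param reports a list of `eval_report` rows (or a single one).
#' @param digits decimal places for the rendered view (default 2, matching
#'   standard calibration-table reporting).
#' @return data.frame, one row per report, numeric cells rounded.
#' @export
render_report <- function(reports, digits = 2) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(parameter = r$parameter, role = r$role, n = r$n,
               rank = r$rank,
               mean = r$mean, sd = r$sd, min = r$min, max = r$max,
               r2 = r$r2, rmse = r$rmse, rpd = r$rpd, sel = r$sel,
               prl = r$prl, rer = r$rer, band = r$band,
               stringsAsFactors = FALSE)))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Build calibration and validation report rows for a fitted model
#'
#' Produces the two standard report rows for one constituent: the
#' cross-validation row (R2cv, RMSECV, RPD, SEL, PRL, RER over the
#' calibration set's held-out predictions) and the external-validation row
#' (same statistics over the validation set predictions).
#'
#' @param model a `pls_model` (see [fit_calibration]).
#' @param cv the `cv_result` from [cross_validate] on the calibration set.
#' @param split a `split_plan`.
#' @param s the raw full-grid [spectra_set] covering all samples.
#' @param ref a `reference_table` with the model's parameter.
#' @param replicates optional replicate-resolved table for SEL.
#' @return list with `calibration` and `validation` `eval_report`s.
#' @export
build_report <- function(model, cv, split, s, ref, replicates = NULL) {
  if (length(split$validation_ids) == 0) stop("validation set is empty")
  par <- model$parameter
  y_cal <- ref[[par]][match(split$calibration_ids, ref$sample_id)]
  y_val <- ref[[par]][match(split$validation_ids, ref$sample_id)]
  if (anyNA(y_cal) || anyNA(y_val))
    stop("split ids missing from reference table")
  rep_cal <- rep_val <- NULL
  if (!is.null(replicates)) {
    rep_cal <- replicates[replicates$sample_id %in% split$calibration_ids, ]
    rep_val <- replicates[replicates$sample_id %in% split$validation_ids, ]
  }
  yhat_val <- predict(model, s[split$validation_ids, ])
  list(
    calibration = eval_report(par, y_cal, cv$predictions, role = "CV",
                              replicates = rep_cal, rank = model$fit$rank),
    validation = eval_report(par, y_val, yhat_val, role = "P",
                             replicates = rep_val, rank = model$fit$rank))
}
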