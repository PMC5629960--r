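#' Default per-constituent model configurations
#'
#' The standard configuration for Italian-ryegrass forage calibration: the
#' scatter-correction method, wavenumber windows and maximum rank per
#' constituent that the calibration study settled on (CP: FD+MSC over
#' 4,247-6,102 cm^-1; NDF: MSC over 4,247-5,450; ADF: FD over 4,247-4,602
#' and 5,446-6,102; WSC: MMN over the same two windows).
#'
#' @param max_rank maximum PLS rank cross-validated per model (default 12).
#' @return Named list per constituent with elements `candidates` (list of
#'   [pretreatment_spec]) and `max_rank`.
#' @export
default_model_config <- function(max_rank = 12) {
  w_cp <- list(c(4247, 6102))
  w_ndf <- list(c(4247, 5450))
  w_two <- list(c(4247, 4602), c(5446, 6102))
  list(
    CP = list(candidates = list(pretreatment_spec(c("FD", "MSC"), w_cp)),
              max_rank = max_rank),
    NDF = list(candidates = list(pretreatment_spec("MSC", w_ndf)),
               max_rank = max_rank),
    ADF = list(candidates = list(pretreatment_spec("FD", w_two)),
               max_rank = max_rank),
    WSC = list(candidates = list(pretreatment_spec("MMN", w_two)),
               max_rank = max_rank))
}

#' The full pretreatment palette as grid-search candidates
#'
#' All seven single pretreatments, the raw spectra, and the first-derivative
#' combinations FD+MSC, FD+SLS, FD+SNV, over a common set of windows.
#'
#' @param windows window list applied to every candidate (NULL = full grid).
#' @return list of [pretreatment_spec] objects.
#' @export
pretreatment_palette <- function(windows = NULL) {
  base <- list(character(0), "SNV", "MSC", "MMN", "FD", "SED", "SLS", "COE",
               c("FD", "MSC"), c("FD", "SLS"), c("FD", "SNV"))
  lapply(base, pretreatment_spec, windows = windows)
}

#' Run the full calibration workflow
#'
#' For each configured constituent: one joint range-based split, candidate
#' grid search by cross-validated RMSECV, final fit at the chosen rank, and
#' calibration + external-validation report rows.  A constituent whose
#' candidates all fail is recorded and the others proceed.  With `outdir`
#' set, writes `split.csv`, `report_calibration.csv`,
#' `report_validation.csv`, `models/<parameter>.json` and `run.log`.
#'
#' @param spectra raw full-grid [spectra_set].
#' @param reference a `reference_table` covering the configured parameters.
#' @param config per-constituent configuration (see [default_model_config]).
#' @param n_cal,n_val split sizes (defaults: the conventional 93/30 ratio
#'   scaled to n).
#' @param scheme,k cross-validation scheme passed to [cross_validate]
#'   (default leave-one-out).
#' @param replicates optional replicate table for SEL columns.
#' @param outdir output directory, or NULL to skip writing.
#' @return A `calibration_run`: list with `split`, per-parameter `models`,
#'   `cv`, `reports`, `grid` tables, a decision `log`, and rendered
#'   `calibration_table` / `validation_table` data.frames.
#' @export
run_calibration <- function(spectra, reference, config = default_model_config(),
                            n_cal = NULL, n_val = NULL,
                            scheme = c("LOO", "kfold"), k = 10,
                            replicates = NULL, outdir = NULL) {
  scheme <- match.arg(scheme)
  al <- align_samples(spectra, reference)
  spectra <- al$spectra; reference <- al$reference
  n <- length(spectra$sample_ids)
  if (is.null(n_val)) n_val <- round(n * 30 / 123)
  if (is.null(n_cal)) n_cal <- n - n_val
  if (is.null(replicates)) replicates <- attr(reference, "replicates")
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  say("n = ", n, "; split ", n_cal, "/", n_val, "; CV scheme = ", scheme)
  split <- range_split(reference, n_cal, n_val)
  s_cal <- spectra[split$calibration_ids, ]
  models <- list(); cvs <- list(); reports <- list(); grids <- list()
  for (par in names(config)) {
    cfgp <- config[[par]]
    if (!par %in% names(reference)) {
      say(par, ": not in reference table, skipped")
      next
    }
    y_cal <- reference[[par]][match(split$calibration_ids,
                                    reference$sample_id)]
    res <- tryCatch({
      grid <- grid_search(s_cal, y_cal, cfgp$candidates, cfgp$max_rank,
                          scheme = scheme, k = k)
      if (!any(grid$ok)) stop("all pretreatment candidates failed: ",
                              paste(unique(grid$error), collapse = "; "))
      win_spec <- attr(grid, "specs")[[which(grid$ok)[1]]]
      win_cv <- attr(grid, "cv")[[which(grid$ok)[1]]]
      say(par, ": winner ", grid$pretreatment[which(grid$ok)[1]],
          ", rank ", win_cv$rank,
          ", RMSECV ", format(min(win_cv$rmsecv), digits = 4))
      model <- fit_calibration(s_cal, y_cal, win_spec, win_cv$rank, par)
      rep <- build_report(model, win_cv, split, spectra, reference,
                          replicates = replicates)
      list(model = model, cv = win_cv, report = rep, grid = grid)
    }, error = function(e) {
      say(par, ": FAILED (", conditionMessage(e), ")")
      NULL
    })
    if (is.null(res)) next
    models[[par]] <- res$model
    cvs[[par]] <- res$cv
    reports[[par]] <- res$report
    grids[[par]] <- res$grid
  }
  cal_tab <- render_report(lapply(reports, `[[`, "calibration"))
  val_tab <- render_report(lapply(reports, `[[`, "validation"))
  out <- structure(list(split = split, models = models, cv = cvs,
                        reports = reports, grid = grids, log = log,
                        calibration_table = cal_tab,
                        validation_table = val_tab),
                   class = "calibration_run")
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "models"), recursive = TRUE,
               showWarnings = FALSE)
    write_split(split, file.path(outdir, "split.csv"))
    utils::write.csv(cal_tab, file.path(outdir, "report_calibration.csv"),
                     row.names = FALSE)
    utils::write.csv(val_tab, file.path(outdir, "report_validation.csv"),
                     row.names = FALSE)
    for (par in names(models))
      write_pls_model(models[[par]],
                      file.path(outdir, "models", paste0(par, ".json")))
    writeLines(log, file.path(outdir, "run.log"))
  }
  out
}

#' @export
print.calibration_run <- function(x, ...) {
  cat("<calibration_run> ", length(x$models), " model(s)\n", sep = "")
  cat("\nCross-validation:\n")
  print(x$calibration_table, row.names = FALSE)
  cat("\nExternal validation:\n")
  print(x$validation_table, row.names = FALSE)
  invisible(x)
}

#' Predict constituents for new spectra from persisted models
#'
#' Applies one or more persisted calibration models to a spectra set.
#' Predictions outside a model's training range are flagged in the
#' `<parameter>_extrapolated` column, and refused (error) unless
#' `allow_extrapolation = TRUE`.
#'
#' @param model_paths character vector of JSON model paths (or a list of
#'   `pls_model` objects).
#' @param spectra a [spectra_set] (raw).
#' @param allow_extrapolation permit out-of-training-range predictions
#'   (flagged rather than refused).
#' @return data.frame: `sample_id`, one prediction column per model and one
#'   logical `_extrapolated` flag column per model.
#' @export
run_predict <- function(model_paths, spectra, allow_extrapolation = FALSE) {
  models <- lapply(model_paths, function(m)
    if (inherits(m, "pls_model")) m else read_pls_model(m))
  out <- data.frame(sample_id = spectra$sample_ids,
                    stringsAsFactors = FALSE)
  for (m in models) {
    yhat <- predict(m, spectra)
    extra <- yhat < m$y_range[1] | yhat > m$y_range[2]
    if (any(extra) && !allow_extrapolation)
      stop(m$parameter, ": prediction outside the calibration range [",
           format(m$y_range[1]), ", ", format(m$y_range[2]), "] for ",
           paste(spectra$sample_ids[extra], collapse = ", "),
           "; rerun with allow_extrapolation = TRUE to flag instead")
    out[[m$parameter]] <- yhat
    out[[paste0(m$parameter, "_extrapolated")]] <- extra
  }
  out
}

#' Read a pipeline configuration from YAML
#'
#' Minimal schema: optional `split: {n_cal, n_val}`, `cv: {scheme, k}`,
#' `max_rank`, and per-constituent blocks
#' `models: {CP: {steps: [FD, MSC], windows: [[4247, 6102]]}, ...}`.
#'
#' @param path YAML file path.
#' @return list with `config` (for [run_calibration]) plus `n_cal`, `n_val`,
#'   `scheme`, `k`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  doc <- yaml::read_yaml(path)
  max_rank <- if (is.null(doc$max_rank)) 12 else doc$max_rank
  config <- lapply(doc$models, function(m) {
    windows <- if (is.null(m$windows)) NULL else
      lapply(m$windows, as.numeric)
    list(candidates = list(pretreatment_spec(unlist(m$steps), windows)),
         max_rank = if (is.null(m$max_rank)) max_rank else m$max_rank)
  })
  list(config = config,
       n_cal = doc$split$n_cal, n_val = doc$split$n_val,
       scheme = if (is.null(doc$cv$scheme)) "LOO" else doc$cv$scheme,
       k = if (is.null(doc$cv$k)) 10 else doc$cv$k)
}
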