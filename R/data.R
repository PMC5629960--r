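#' Published-style reference statistics for Italian ryegrass calibration
#'
#' Summary and diagnostic statistics of a forage-quality NIRS calibration of
#' Italian ryegrass (*Lolium multiflorum*), shipped as plain CSVs under
#' `inst/extdata`: per-constituent reference-value summaries (n, mean, SD,
#' min, max in %DM) for a 93/30 calibration/validation split, and the
#' reported cross-validation and external-validation statistics (rank, R2,
#' RMSECV/RMSEP, RPD, SEL, PRL, RER).  These serve as worked-example inputs
#' for the evaluation layer: the ratio statistics can be recomputed from the
#' printed SD/range/RMSE/SEL cells and compared at 2-dp rendering.
#'
#' @return list of three data.frames: `summary`, `calibration`,
#'   `validation`.
#' @export
ryegrass_statistics <- function() {
  path <- function(f) system.file("extdata", f, package = "nirscal",
                                  mustWork = TRUE)
  list(
    summary = utils::read.csv(path("ryegrass_reference_summary.csv"),
                              stringsAsFactors = FALSE),
    calibration = utils::read.csv(path("ryegrass_calibration_statistics.csv"),
                                  stringsAsFactors = FALSE),
    validation = utils::read.csv(path("ryegrass_validation_statistics.csv"),
                                 stringsAsFactors = FALSE))
}
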