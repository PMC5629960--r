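#' Crude protein content from Kjeldahl titration
#'
#' CP (%DM) = (V1 - V2) * C * 1.4007 * 6.25 / M * 100, where V1/V2 are the
#' sample/blank titre volumes (ml) of standard HCl, C its molarity (mol/l),
#' 1.4007 the milliequivalent weight of nitrogen x 100 (mg N per meq, as
#' conventionally tabulated for this assay), 6.25 the average
#' nitrogen-to-protein conversion coefficient and M the sample mass (g).
#' The formula is implemented exactly as conventionally printed for this
#' assay; note that the "x 100" inside the 1.4007 constant and the trailing
#' "x 100" percentage factor are both part of the printed convention and are
#' kept verbatim rather than dimensionally re-derived (the constants are
#' arguments so either audit convention can be run).
#'
#' @param V1,V2 titre volumes (ml), `V1 >= V2`.
#' @param C HCl molarity (mol/l).
#' @param M sample mass (g), > 0.
#' @param meq_N,protein_factor the 1.4007 and 6.25 constants.
#' @return CP in %DM.
#' @export
cp_percent <- function(V1, V2, C, M, meq_N = 1.4007, protein_factor = 6.25) {
  if (any(M <= 0)) stop("sample mass M must be > 0")
  if (any(V1 < V2)) stop("negative titre: V1 < V2")
  (V1 - V2) * C * meq_N * protein_factor / M * 100
}

#' Neutral detergent fiber content
#'
#' NDF (%DM) = (M2 - M1 * C1) / M * 100: residue mass after neutral-detergent
#' extraction (M2, g), corrected for the filter-bag tare (M1, g) times the
#' ash-corrected blank-bag factor (C1), over sample mass (M, g).
#'
#' @param M2 post-extraction organic-matter mass (g).
#' @param M1 bag tare mass (g).
#' @param C1 ash-corrected blank bag factor (dimensionless).
#' @param M sample mass (g), > 0.
#' @return NDF in %DM.
#' @export
ndf_percent <- function(M2, M1, C1, M) {
  if (any(M <= 0)) stop("sample mass M must be > 0")
  if (any(M2 - M1 * C1 < 0))
    stop("assay inconsistency: corrected residue mass is negative")
  (M2 - M1 * C1) / M * 100
}

#' Acid detergent fiber content
#'
#' ADF (%DM) = (M3 - M1 * C1) / M * 100, the acid-detergent analogue of
#' [ndf_percent] with M3 the post-extraction residue mass.
#'
#' @param M3 post-extraction organic-matter mass (g).
#' @inheritParams ndf_percent
#' @return ADF in %DM.
#' @export
adf_percent <- function(M3, M1, C1, M) ndf_percent(M3, M1, C1, M)

#' Water-soluble carbohydrate content
#'
#' WSC (%DM) = 2.34 * (dA + 0.07) / (W * 10), from the colorimetric assay:
#' dA is the blank-corrected absorbance at 620 nm and W the sample mass (g).
#' The kit calibration constants 2.34 and 0.07 are exposed as arguments.
#'
#' @param deltaA absorbance difference, `>= -blank`.
#' @param W sample mass (g), > 0.
#' @param slope,blank kit calibration constants (defaults 2.34, 0.07).
#' @return WSC in %DM.
#' @export
wsc_percent <- function(deltaA, W, slope = 2.34, blank = 0.07) {
  if (any(W <= 0)) stop("sample mass W must be > 0")
  if (any(deltaA < -blank)) stop("absorbance below blank: deltaA < -", blank)
  slope * (deltaA + blank) / (W * 10)
}
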