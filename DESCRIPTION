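Package: nirscal
Title: Near-Infrared Spectroscopy Calibration for Forage Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration workflow for predicting forage quality constituents
    (crude protein, neutral and acid detergent fiber, water-soluble
    carbohydrates, in percent of dry matter) from near-infrared reflectance
    spectra.  Implements the standard chemometric pretreatments (SNV, MSC,
    min-max normalization, Savitzky-Golay derivatives, detrending, offset
    elimination), Kennard-Stone representative subset selection, a range-based
    calibration/validation split, NIPALS PLS1 regression with cross-validated
    rank selection over wavenumber windows, and the full diagnostic layer
    (RMSEC/RMSECV/RMSEP, R2, RPD, RER, SEL, PRL).  Ships a Beer-Lambert
    band-model simulator so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
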