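---
title: "NIRS calibration for forage quality: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIRS calibration for forage quality: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscal)
```

## The problem

Breeding and grazing programs for annual forage grasses such as Italian
ryegrass need four quality constituents measured on many hundreds of
samples: crude protein (CP), neutral and acid detergent fiber (NDF, ADF)
and water-soluble carbohydrates (WSC), all in percent of dry matter (%DM).
Wet chemistry (Kjeldahl digestion, detergent-fiber bags, colorimetric sugar
assays) is accurate but slow; near-infrared reflectance spectroscopy (NIRS)
predicts all four from a single one-minute scan once a calibration has been
built. `nirscal` implements that calibration workflow end to end:

1. spectra on a wavenumber grid (absorbance recorded as log(1/R)),
2. spectral pretreatment (scatter correction, derivatives, detrending),
3. representative-sample selection (Kennard–Stone) and a range-based
   calibration/validation split,
4. PLS1 regression with cross-validated rank selection over restricted
   wavenumber windows,
5. the diagnostic layer used to judge such calibrations: R², RMSEC/RMSECV/
   RMSEP, RPD, RER, SEL and PRL.

A Beer–Lambert band-model simulator generates spectra with the same
statistical structure, so every stage is testable without instrument data.

## Data model

A `spectra_set` holds an n × p absorbance matrix, a strictly increasing
wavenumber axis (cm⁻¹; decreasing input grids are canonicalized on read)
and unique sample ids. The reference side is a `reference_table`: one %DM
value per sample and constituent, optionally with replicate-resolved rows
retained for laboratory-precision estimation. Wide CSV (samples as rows,
wavenumber headers) is the canonical file dialect; a transposed wide layout
and a long three-column layout are also read.

## Pretreatments

Seven per-spectrum transforms cover the standard palette:

| name | effect | notes |
|------|--------|-------|
| SNV  | row-standardize (mean 0, sd 1) | sd uses the n−1 denominator |
| MSC  | regress on a reference spectrum, invert the affine fit | reference = calibration mean, stored with the model |
| MMN  | map row range to [0, 1] | some vendor dialects scale to 2; this package uses [0, 1] |
| FD / SED | Savitzky–Golay 1st/2nd derivative | default window 17 points, polynomial order 2 |
| SLS  | subtract the row's least-squares line | idempotent detrend |
| COE  | subtract the row minimum | offset elimination |

Derivatives are expressed per unit of grid index, not per cm⁻¹ — rank
selection and regression are unaffected by the constant scale, and the
choice keeps results independent of grid spacing conventions. The window
17 / order 2 defaults are common FT-NIR practice; both are configurable.

Combinations such as FD+MSC apply the derivative first and the scatter
correction second, matching the conventional naming order; the order is the
spec of the chain, so any other order is expressible. Wavenumber windows
are applied **after** all steps, on the full grid: this avoids derivative
edge artifacts at window boundaries and makes chains order-deterministic.
SNV and windowing do not commute, so the order is load-bearing and is
locked by a regression test.

## Sample selection and splitting

`kennard_stone()` implements the classic greedy max–min algorithm on
Euclidean distances over column-mean-centered spectra: seed with the most
distant pair, then repeatedly add the sample farthest from the selected
set. Ties break to the smallest row index, making the output a
deterministic ordered list with the prefix property (the first k picks of a
k+1 selection equal the k-selection). The classic max-distance-pair seeding
is used; mean-seeded variants exist but are not the default.

`range_split()` concretizes "split according to the range of the chemical
values": samples are ranked along the first principal direction of the
standardized constituent matrix, every constituent's global minimum and
maximum are pinned to the calibration set, and the requested number of
validation samples is taken at evenly spaced positions along the ranked
interior. The conventional sizes are 93/30 for n = 123; the implementation
takes any minority validation size and always produces exact counts. One
joint split serves all four constituents (the per-constituent summary
tables of such studies report identical n, implying a joint split).

## PLS1 and rank selection

Each constituent gets its own single-response NIPALS PLS1 model (not
PLS2): X and y are mean-centered (no autoscaling — standard for spectra;
an autoscale flag exists), components extracted by deflation, coefficients
recovered as W(PᵀW)⁻¹q. Full-rank PLS1 equals ordinary least squares, which
the tests assert against a normal-equations oracle; on exactly noiseless
systems the factorization truncates at the last informative component.

The rank ("number of principal components used for calibration") is chosen
by cross-validation: leave-one-out by default, contiguous-block k-fold for
speed. The chosen rank is the strict argmin of RMSECV with ties to the
smaller rank — no F-test parsimony heuristic, which is a documented
deviation risk against vendor software that applies one. `grid_search()`
runs the candidate pretreatments (and windows) through the same
cross-validation and ranks them by best RMSECV; failing candidates (e.g. a
degenerate spectrum under a transform) are recorded, not fatal.

Fitted models carry full provenance — pretreatment chain, MSC reference,
full and window-restricted grids, centering vectors, coefficients, the
training-response range — and serialize to JSON at full double precision,
so predictions reproduce bit-for-bit across sessions. Prediction applies
the model's own pretreatment with the stored scatter reference; spectra on
a different but covering grid are linearly interpolated, and predictions
outside the training range are refused unless extrapolation is explicitly
allowed.

## The statistic layer

For reference values y and predictions ŷ:

- RMSE = √(mean (y − ŷ)²), reported as RMSEC (training), RMSECV
  (cross-validation) or RMSEP (external validation);
- R² = 1 − SSE/SST (about the mean of y);
- RPD = SD(y)/RMSE — > 3 successful, > 4 excellent for screening;
- RER = range(y)/RMSE — > 10 recommended for screening;
- SEL = pooled within-sample replicate standard deviation,
  √(ΣᵢΣⱼ(yᵢⱼ−ȳᵢ)²/Σᵢ(rᵢ−1)) — the source report does not print its SEL
  formula, so the standard laboratory-precision estimator is used;
- PRL = RMSE/SEL — < 2 means predictions are within twice lab precision.

All ratios are carried at full precision and rounded only at render time
(2 dp), because published tables of this kind mix rounded inputs with
unrounded intermediates: recomputing the ratios from printed SD/range/RMSE/
SEL cells of the shipped ryegrass tables reproduces every NDF and ADF cell
and most WSC cells exactly at 2 dp, while the CP cells (and WSC's
calibration PRL) differ in the last digit — see
`analysis/04_worked_statistics.R`. The guideline banding (excellent /
successful / intermediate / inadequate) follows the screening scale:
excellent above R² 0.95 and RPD 4, successful from R² 0.9 and RPD 3,
inadequate below R² 0.7 and RPD 1.75.

A perfect fit (RMSE = 0) would make RPD/RER infinite; reports flag this as
an overflow rather than erroring.

## Wet-chemistry determinations

The four reference determinations are implemented exactly as conventionally
printed: CP = (V1−V2)·C·1.4007·6.25/M·100 (Kjeldahl), NDF/ADF =
(residue − tare·bag factor)/M·100 (detergent-fiber bags), WSC =
2.34·(ΔA+0.07)/(10·W) (colorimetric kit). The CP equation's constant
1.4007 is tabulated as "milliequivalent weight of N × 100" *and* the
equation carries a trailing ×100; the two cannot both be dimensionally
canonical (the canonical %DM value is 100-fold smaller). The printed form
is implemented verbatim and the constants are exposed as arguments so
either audit convention can be run. The fiber protocol also defines a C2
factor it never uses; it has no home in any implemented equation and is
deliberately left out.

## The synthetic generator

`simulate_nirs()` draws, per sample i and wavenumber ν:

A_i(ν) = b_i·(Σ_c conc_ic·band_c(ν) + bg(ν) + base_i + slope_i·u(ν)) + a_i + ε_i(ν)

with Gaussian constituent bands placed at the main absorption features of
dried forage (C–H, N–H, O–H combination/overtone bands near 4,240, 4,740,
5,170, 5,800 and 6,800 cm⁻¹), a broad fixed background, multiplicative
scatter b_i ~ N(1, 0.10), additive offsets (sd 0.05), a mild baseline tilt
(sd 0.01 over the grid), and white absorbance noise (sd 0.002). Defaults:
123 samples on the 4,000–12,500 cm⁻¹ / 2,203-point grid, concentrations
uniform in the field ranges (CP 4.45–30.60, NDF 21.29–60.47,
ADF 11.66–36.17, WSC 3.95–51.52 %DM), independently by default — an
optional Gaussian-copula correlation matrix captures the CP/NDF
anti-correlation of real maturity series, which matters for split balance.
Three replicate measurements per sample are generated as truth + N(0, 1.5)
noise, the SEL scale of routine wet chemistry.

Two semantics deserve emphasis. First, the reference table's per-sample
value is the generating truth; the noisy replicates feed only the SEL
estimator. This mirrors the internal structure of published calibrations
whose RMSECV is *below* their SEL, which is only coherent if the
calibration reference is effectively more precise than a single replicate.
Second, the generator is linear Beer–Lambert with white noise: it emulates
band positions, scatter and replicate error, but not instrument line
shapes, wavelength-dependent noise, moisture-driven band shifts or the
nonlinear particle-size effects of real reflectance spectra. Passing
recovery tests therefore demonstrate that the pipeline's algebra and
decision logic are correct under the assumed data model — not that any
particular real data set will reach the same statistics. Notably, under
these conditions the FD+MSC chain leaves a little residual multiplicative
error on the CP constituent (validation R² typically 0.94–0.98 across
seeds), somewhat below the 0.99 reported for the real instrument data the
configuration imitates; the synthetic scatter is deliberately not tuned to
close that gap.

## Numerical choices and degenerate inputs

- Constant spectra make SNV/MMN undefined: both error naming the samples.
- MSC with a constant reference, zero fitted slope, empty windows,
  invalid ranks, mismatched sample ids, out-of-range %DM values and
  sub-minimal replicate counts all raise early, specific errors.
- Kennard–Stone ties (duplicate points) resolve by smallest row index;
  the seed pair orders by row.
- The RMSECV argmin tie-break is the smaller rank.
- Range-split ranking ties resolve by row order; a zero-variance
  constituent column contributes zero to the ranking rather than NaN.
- Round-trips: spectra CSV read∘write is the identity to 1e-9; model JSON
  read∘write reproduces predictions to machine precision.

## Problem sizes used by the test and acceptance runs

The shipped tests run the generator at reduced sizes chosen to exercise
every code path with comfortable margins: unit tests mostly use 40–60
samples × 120–250 grid points; the recovery experiments use 120 samples ×
400 points over 10 seeds with 10-fold cross-validation; the full-workflow
checks use the complete study geometry (123 × 2,203) once. These sizes are
the package's own choice of a thorough-but-quick default; all stages accept
the full geometry throughout, as `analysis/` demonstrates.

## Known limitations

- The derivative is per grid index; exporting coefficients to software
  that differentiates per cm⁻¹ requires rescaling by the grid step.
- The range-split is one deterministic concretization of a one-sentence
  published procedure; other implementations (e.g. vendor software) will
  produce different-but-equivalent splits, so error statistics should be
  compared at the level of quality bands, not digits.
- No JCAMP-DX reader; CSV dialects only.
- No orthogonal signal correction, EMSC, wavelets, PLS2, MLR/PCR backends,
  or variable selection beyond fixed windows — outside this workflow's
  palette.
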