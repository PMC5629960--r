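# nirscal

Near-infrared spectroscopy (NIRS) calibration for forage quality.

Forage breeding and grazing management need crude protein (CP), neutral
detergent fiber (NDF), acid detergent fiber (ADF) and water-soluble
carbohydrates (WSC) — all in % of dry matter — measured on far more samples
than wet chemistry can handle. NIRS solves this once a calibration exists:
a model that maps an absorbance spectrum, recorded as log(1/R) over
4,000–12,500 cm⁻¹, to the four constituent concentrations. `nirscal` is
that calibration workflow as a tested R package, aimed at plant phenotyping
and feed-lab users who want the full chain — pretreatment, sample
selection, regression, diagnostics — reproducible and scriptable rather
than locked inside vendor software.

## What it implements

- **Spectral pretreatment**: SNV, MSC, min–max normalization,
  Savitzky–Golay first/second derivatives, straight-line subtraction,
  constant-offset elimination, their FD+ combinations, and wavenumber-window
  restriction (applied after the transforms).
- **Sample selection**: Kennard–Stone greedy max–min selection, and a
  deterministic range-based calibration/validation split (per-constituent
  extremes pinned to calibration; conventional sizes 93/30).
- **Regression**: NIPALS PLS1 per constituent, y = ȳ + (x − x̄)ᵀb with
  b = W(PᵀW)⁻¹q, rank chosen as the argmin of RMSECV under leave-one-out or
  blocked k-fold cross-validation; grid search over pretreatment
  candidates; models persisted as JSON with full provenance.
- **Diagnostics**: R² = 1 − SSE/SST, RMSEC/RMSECV/RMSEP,
  RPD = SD/RMSE, RER = (max−min)/RMSE, SEL (pooled within-replicate sd),
  PRL = RMSE/SEL, and the screening quality bands (successful: R² ≥ 0.9,
  RPD ≥ 3; excellent: R² > 0.95, RPD > 4).
- **Wet-chemistry arithmetic**: the Kjeldahl CP, detergent-fiber NDF/ADF
  and colorimetric WSC determination equations, as printed, with constants
  exposed for dimensional audits.
- **A Beer–Lambert simulator** of study-sized data sets (123 samples ×
  2,203 points, bands near 4,240/4,740/5,170/5,800/6,800 cm⁻¹, per-sample
  scatter, replicate noise) so the whole pipeline is testable offline.

See `vignettes/nirs-calibration.Rmd` for the models, parameter choices and
limitations, and `analysis/` for the numbered workflow scripts
(simulate → calibrate → validate → worked statistics).

## Worked example

```r
library(nirscal)

cfg <- sim_config(n_samples = 123, n_points = 600, seed = 42)
sim <- simulate_nirs(cfg)
run <- run_calibration(sim$spectra, sim$reference,
                       default_model_config(max_rank = 12),
                       scheme = "kfold", k = 10)
run$validation_table
```

```
n = 123; split 93/30; CV scheme = kfold
CP: winner FD+MSC, rank 4, RMSECV 1.549
NDF: winner MSC, rank 4, RMSECV 1.042
ADF: winner FD, rank 6, RMSECV 1.098
WSC: winner MMN, rank 4, RMSECV 1.546
 parameter rank   r2 rmse   rpd  sel  prl   rer      band
        CP    4 0.96 1.32  5.26 1.49 0.88 19.34 excellent
       NDF    4 0.99 0.94 10.43 1.53 0.61 31.59 excellent
       ADF    6 0.97 1.13  6.41 1.58 0.72 20.74 excellent
       WSC    4 0.99 1.47 11.07 1.53 0.96 29.80 excellent
```

Reading the CP row: on the 30 held-out validation samples the model
predicts CP with an error (RMSEP) of 1.32 %DM; that error is 5.26× smaller
than the natural spread of the samples (RPD), covers the observed range
19 times (RER), and is below the wet-chemistry replicate precision
(PRL = 0.88 < 1), which places the model in the "excellent" screening
band. The per-constituent winners (CP FD+MSC, NDF MSC, ADF FD, WSC MMN,
each over its wavenumber window) and the cross-validated rank are logged
per run.

Real data enters the same way: `read_spectra("spectra.csv")` (wide CSV,
sample ids + wavenumber headers) and `read_reference("chem.csv")`, then
`run_calibration(...)`, `run_predict(models, new_spectra)`.

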