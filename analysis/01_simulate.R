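#!/usr/bin/env Rscript
# Generate the synthetic study data set: 123 forage samples on the
# 4,000-12,500 cm^-1 / 2,203-point FT-NIR grid, with CP/NDF/ADF/WSC drawn
# from the field concentration ranges, per-sample scatter, absorbance noise
# and triplicate laboratory replicates.  Writes the same wide-CSV formats
# the calibration stage reads.  (Synthetic stand-in: no instrument data is
# downloaded or shipped.)

library(nirscal)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260929)
sim <- simulate_nirs(cfg)

write_spectra(sim$spectra, file.path(out, "spectra_synthetic.csv"))
write.csv(as.data.frame(sim$reference),
          file.path(out, "reference_synthetic.csv"), row.names = FALSE)
write.csv(sim$replicates, file.path(out, "replicates_synthetic.csv"),
          row.names = FALSE)
jsonlite::write_json(sim$truth, file.path(out, "truth_synthetic.json"),
                     digits = NA, dataframe = "columns")

cat("samples:", length(sim$spectra$sample_ids),
    " points:", length(sim$spectra$wavenumbers), "\n")
for (p in c("CP", "NDF", "ADF", "WSC"))
  cat(sprintf("%-4s range %.2f-%.2f %%DM (SEL over triplicates %.2f)\n",
              p, min(sim$reference[[p]]), max(sim$reference[[p]]),
              sel(sim$replicates, p)))
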