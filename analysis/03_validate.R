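#!/usr/bin/env Rscript
# External validation from the persisted artefacts alone: reload the JSON
# models and the split, predict the held-out validation samples, and verify
# the rebuilt statistics against the report written by 02_calibrate.R.
# Writes per-sample measured-vs-predicted pairs for scatter plotting.

library(nirscal)

spectra <- read_spectra("results/data/spectra_synthetic.csv")
reference <- read_reference("results/data/reference_synthetic.csv")
split <- read.csv("results/run/split.csv")
val_ids <- split$sample_id[split$set == "validation"]

models <- file.path("results/run/models",
                    c("CP.json", "NDF.json", "ADF.json", "WSC.json"))
preds <- run_predict(models, spectra[val_ids, ], allow_extrapolation = TRUE)

pairs <- merge(preds, as.data.frame(reference), by = "sample_id",
               suffixes = c("_pred", "_lab"))
write.csv(pairs, "results/run/validation_predictions.csv", row.names = FALSE)

reported <- read.csv("results/run/report_validation.csv")
for (p in c("CP", "NDF", "ADF", "WSC")) {
  y <- pairs[[paste0(p, "_lab")]]
  yhat <- pairs[[paste0(p, "_pred")]]
  r <- eval_report(p, y, yhat, role = "P")
  stopifnot(round(r$r2, 2) == reported$r2[reported$parameter == p])
  cat(sprintf("%-4s R2v %.2f RMSEP %.2f RPD %.2f RER %.2f [%s]\n",
              p, r$r2, r$rmse, r$rpd, r$rer, r$band))
}
cat("\nrebuilt statistics agree with results/run/report_validation.csv\n")

# optional figures: regression-coefficient traces and measured-vs-predicted
# scatter, written as PNGs (never consumed downstream)
fig_dir <- "results/run/figures"
dir.create(fig_dir, showWarnings = FALSE)
for (p in c("CP", "NDF", "ADF", "WSC")) {
  m <- read_pls_model(file.path("results/run/models", paste0(p, ".json")))
  png(file.path(fig_dir, paste0("coefficients_", p, ".png")), 900, 500)
  plot(m$wavenumbers, m$fit$coef, type = "h", col = "steelblue",
       xlab = "wavenumber (cm-1)", ylab = "regression coefficient",
       main = paste(p, "model coefficients"))
  abline(h = 0, col = "grey40")
  dev.off()
  png(file.path(fig_dir, paste0("validation_", p, ".png")), 500, 500)
  y <- pairs[[paste0(p, "_lab")]]; yhat <- pairs[[paste0(p, "_pred")]]
  plot(y, yhat, pch = 19, col = "darkgreen",
       xlab = "wet chemistry (%DM)", ylab = "NIRS predicted (%DM)",
       main = paste(p, "external validation"))
  abline(0, 1, col = "grey40")
  dev.off()
}
cat("figures written under", fig_dir, "\n")
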