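#!/usr/bin/env Rscript
# Global multi-cycle SPR fits of the simulated cycle sets: recover the
# rate constants and unresponsive-host fraction jointly across all
# effector concentrations, then extract the effective-rate curve, the
# constrained hyperbolic summary (K_1/2) and the fold acceleration.

suppressPackageStartupMessages(library(fdkin))
dir.create("results", showWarnings = FALSE)

manifest <- read.csv("results/01_simulated_datasets.csv")

rows <- lapply(seq_len(nrow(manifest)), function(i) {
  m <- manifest[i, ]
  cs <- read_cycleset(m$file, sub("\\.csv$", "_truth.json", m$file))
  rep <- suppressWarnings(characterize_forward(cs))
  data.frame(dataset = m$dataset, fold_true = m$fold_true,
             fold_fitted = rep$fold_acceleration,
             fold_rel_err = abs(rep$fold_acceleration / m$fold_true - 1),
             k_off_T_H = rep$params$k_off_T_H,
             k_off_T_HE = rep$params$k_off_T_HE,
             f_responsive = rep$params$f_responsive,
             K_half_M = rep$K_half, rms = rep$rms)
})
out <- do.call(rbind, rows)
write.csv(out, "results/03_global_fits.csv", row.names = FALSE)

cat("Global fit recovery of the fold acceleration:\n")
print(out[, c("dataset", "fold_true", "fold_fitted", "fold_rel_err",
              "K_half_M")], row.names = FALSE)
cat(sprintf("All folds recovered within %.2g%%.\n",
            100 * max(out$fold_rel_err)))
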