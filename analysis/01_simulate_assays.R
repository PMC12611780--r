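#!/usr/bin/env Rscript
# Generate the synthetic assay datasets used throughout the analysis:
# multi-cycle SPR cycle sets at the four characteristic fold
# accelerations of the designed systems (20x to 5,700x), an FP titration,
# a reverse facilitated-dissociation course set and a sensor-activation
# luminescence trace. Bulky datasets go to scratch/; results/ records the
# manifest with the embedded ground truth.

suppressPackageStartupMessages(library(fdkin))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

folds <- c(20, 1500, 2400, 5700)
design <- experiment_design(n_conc = 8, dt = 10)  # 2 h phases, 10 s sampling

manifest <- do.call(rbind, lapply(seq_along(folds), function(i) {
  fold <- folds[i]
  params <- list(k_off_T_H = 1e-5, k_off_T_HE = 1e-5 * fold,
                 k_on_TH_E = 1e5, k_off_TH_E = 1e-4, k_off_T_Hn = 1e-5,
                 f_responsive = 0.95)
  cs <- suppressWarnings(gen_cycleset(params, design,
                                      noise_model(seed = 1000 + i)))
  csv <- sprintf("scratch/cycleset_fold%d.csv", fold)
  json <- sprintf("scratch/cycleset_fold%d_truth.json", fold)
  write_cycleset(cs, csv, json)
  tr <- attr(cs, "truth")
  data.frame(dataset = sprintf("cycleset_fold%d", fold),
             fold_true = fold, k_off_T_H = tr$k_off_T_H,
             k_off_T_HE = tr$k_off_T_HE, f_responsive = tr$f_responsive,
             sigma = tr$sigma, n_cycles = length(unique(cs$cycle)),
             n_points = nrow(cs), file = csv)
}))

# FP titration at a host:effector affinity of 10 nM, 0.5 nM probe
fp <- gen_fp_titration(1e-8, 5e-10, P0 = 40, P1 = 160, top_conc = 1e-6,
                       noise = noise_model(seed = 1101))
write.csv(fp, "scratch/fp_titration.csv", row.names = FALSE)

# reverse facilitated dissociation: effector chased off by target
rev_truth <- list(k_off_TH_E = 1e-2, K_half = 1e-6, k_off_HE = 1e-5,
                  S0 = 30, S1 = 150, T_conc = c(0, 1e-6 / 2^(8:0)))
rev_courses <- gen_competition_courses("reverse", rev_truth, dt = 5,
                                       noise = noise_model(seed = 1102))
write_time_courses_csv(rev_courses, "scratch/reverse_fd_courses.csv")

# sensor activation with a 30 s half-time
lum <- gen_competition_courses("luminescence",
                               list(half_time = 30, S0 = 5, S1 = 95),
                               noise = noise_model(seed = 1103))
write_time_courses_csv(lum, "scratch/sensor_activation.csv")

write.csv(manifest, "results/01_simulated_datasets.csv", row.names = FALSE)
cat("Simulated", nrow(manifest), "multi-cycle SPR datasets (",
    paste(folds, collapse = "x, "), "x fold acceleration),\n",
    "one FP titration, one reverse-FD course set and one sensor trace.\n")
cat("Manifest: results/01_simulated_datasets.csv; data under scratch/.\n")
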