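#!/usr/bin/env Rscript
# Parameter-recovery sweep: random ground-truth parameter sets drawn
# log-uniformly over the plausible ranges of the designed systems, each
# turned into a synthetic multi-cycle experiment at 0.5% noise and refit
# globally. Scores the fraction of key parameters recovered within 5%.

suppressPackageStartupMessages(library(fdkin))
dir.create("results", showWarnings = FALSE)

sweep <- recover_sweep(n_sets = 12, seed = 5001, noise_frac = 0.005,
                       design = experiment_design(dt = 10))
write.csv(sweep, "results/05_parameter_recovery.csv", row.names = FALSE)

ok <- c(k_off_T_H = mean(sweep$rel_err_k_off_T_H < 0.05),
        k_off_T_HE = mean(sweep$rel_err_k_off_T_HE < 0.05),
        f_responsive = mean(sweep$rel_err_f_responsive < 0.05))
pooled <- mean(c(sweep$rel_err_k_off_T_H, sweep$rel_err_k_off_T_HE,
                 sweep$rel_err_f_responsive) < 0.05)
cat("Fraction of estimates within 5% of truth (12 random systems):\n")
print(round(ok, 3))
cat(sprintf("Pooled across the three parameters: %.1f%% within 5%%.\n",
            100 * pooled))
cat(sprintf("Median relative errors: %.2g%% (k_off_T_H), %.2g%% (k_off_T_HE), %.2g%% (f_responsive).\n",
            100 * median(sweep$rel_err_k_off_T_H),
            100 * median(sweep$rel_err_k_off_T_HE),
            100 * median(sweep$rel_err_f_responsive)))
# systems whose accelerated off-rate outruns effector binding at the top
# concentration leave the plateau extrapolated; flag them
wide <- sweep[sweep$rel_err_k_off_T_HE >= 0.05, "set"]
if (length(wide))
  cat("Sets", paste(wide, collapse = ", "),
      "have k_eff plateaus above the sampled effector range",
      "(K_1/2 > top [E]); their accelerated off-rates are extrapolated",
      "and carry wide intervals.\n")
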