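#!/usr/bin/env Rscript
# Mechanism discrimination: a flexible effector that engages the closed
# complex directly (induced fit) shows an apparent on-rate growing
# linearly with concentration; a rigid effector that must await the
# conformational opening (conformational selection) shows a hyperbolic
# series saturating at the switching rate. Twenty replicate synthetic
# dose series per mechanism are classified by AICc-based law selection.

suppressPackageStartupMessages(library(fdkin))
dir.create("results", showWarnings = FALSE)

rates <- rate_constants(
  k_on_TH = 1e5, k_off_TH = 9e-5, k_on_HE = 0, k_off_HE = 0,
  k_on_THE_viaE = 1e5, k_off_THE_toE = 5e-5,
  k_on_THE_viaT = 0, k_off_THE_toT = 0,
  k_switch = 2e-3, k_unswitch = 5e-2)
E_grid <- 4e-6 / 2^(7:0)

rows <- list()
for (topo in c("induced_fit", "conformational_selection")) {
  for (r in 1:20) {
    s <- gen_association_series(topo, rates, E_grid,
                                noise = noise_model(seed = 4000 +
                                                      100 * (topo ==
                                                               "induced_fit") +
                                                      r))
    sel <- select_rate_law(s$effector_conc_M, s$k_app)
    k_sat <- if (sel$law == "hyperbolic")
      sel$hyperbolic$params[["k_max"]] + sel$hyperbolic$params[["k_base"]]
    else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      topology = topo, replicate = r, law_selected = sel$law,
      delta_aicc = sel$delta_aicc, k_saturation = k_sat)
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/04_mechanism_discrimination.csv", row.names = FALSE)

tab <- table(out$topology, out$law_selected)
print(tab)
correct <- sum(out$law_selected[out$topology == "induced_fit"] == "linear") +
  sum(out$law_selected[out$topology == "conformational_selection"] ==
        "hyperbolic")
cat(sprintf("Correct mechanism calls: %d/40.\n", correct))
ks <- out$k_saturation[out$topology == "conformational_selection"]
cat(sprintf(
  "Hyperbolic saturation rate %.3g s^-1 (mean) vs k_switch = 2e-3 s^-1.\n",
  mean(ks, na.rm = TRUE)))
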