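# shared fixtures: a representative chip parameter set and a reduced
# sampling design that keeps multi-fit tests fast without degrading
# recovery (coarser 10 s sampling over the same 2 h phases)

chip_params <- function(fold = 100, k_off_T_H = 1e-5, k_on = 1e5,
                        f_responsive = 0.95) {
  list(k_off_T_H = k_off_T_H, k_off_T_HE = k_off_T_H * fold,
       k_on_TH_E = k_on, k_off_TH_E = 1e-4, k_off_T_Hn = k_off_T_H,
       f_responsive = f_responsive)
}

fast_design <- function(...) experiment_design(dt = 10, ...)

# full rate set used for solution-phase network tests
full_rates <- function() {
  rate_constants(
    k_on_TH = 1e5, k_off_TH = 9e-5, k_on_HE = 1e6, k_off_HE = 5e-6,
    k_on_THE_viaE = 1e5, k_off_THE_toE = 5e-5,
    k_on_THE_viaT = 1e4, k_off_THE_toT = 5e-2,
    k_switch = 2e-3, k_unswitch = 5e-2)
}
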