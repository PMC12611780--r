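#' Linear apparent-rate law for effector binding
#'
#' Pseudo-first-order binding of an effector to the target:host complex:
#' `k_app = k_on * [E] + k_off`. This is the law observed when effector
#' binding is not rate-limited by a conformational step (induced fit with a
#' flexible effector).
#'
#' @param E_conc effector concentration (M).
#' @param k_on association rate constant (M^-1 s^-1).
#' @param k_off dissociation rate constant (s^-1).
#' @return Apparent rate constant (s^-1).
#' @export
kapp_linear <- function(E_conc, k_on, k_off) {
  stopifnot(all(E_conc >= 0), k_on >= 0, k_off >= 0)
  k_on * E_conc + k_off
}

#' Slow relaxation rate of binding by conformational selection
#'
#' For the three-state scheme `TH_X <-> TH_Y`, `TH_Y + E <-> THE` under
#' pseudo-first-order effector concentration, the observed slow relaxation
#' rate constant is
#' \deqn{k_{app} = \tfrac12 (k_s + k_u + k_{on}[E] + k_{off})
#'   - \tfrac12 \sqrt{(k_s + k_u - k_{on}[E] - k_{off})^2
#'   + 4 k_u k_{on}[E]}}
#' It saturates at `k_switch` for large `[E]`, which is how a hyperbolic
#' apparent on-rate series identifies a rate-limiting conformational step.
#'
#' @param E_conc effector concentration (M); vectorized.
#' @param k_switch TH_X -> TH_Y rate (s^-1).
#' @param k_unswitch TH_Y -> TH_X rate (s^-1).
#' @param k_on effector on-rate to the open state (M^-1 s^-1).
#' @param k_off effector off-rate from the ternary complex (s^-1).
#' @return Apparent (slow relaxation) rate constant (s^-1).
#' @export
kapp_conformational_selection <- function(E_conc, k_switch, k_unswitch,
                                          k_on, k_off) {
  stopifnot(all(E_conc >= 0), k_switch >= 0, k_unswitch >= 0,
            k_on >= 0, k_off >= 0)
  a <- k_switch + k_unswitch
  b <- k_on * E_conc + k_off
  0.5 * (a + b) - 0.5 * sqrt((a - b)^2 + 4 * k_unswitch * k_on * E_conc)
}

#' Hyperbolic apparent-rate law
#'
#' `k = k_max * c / (K_half + c) + k_base`: the saturating dependence of an
#' effective rate constant on the concentration of the species driving it,
#' used both for facilitated target dissociation versus effector
#' concentration and for reverse facilitated effector dissociation versus
#' target concentration.
#'
#' @param conc driving concentration (M); vectorized.
#' @param k_max maximal rate increase at saturation (s^-1).
#' @param K_half concentration of half-maximal rate increase (M), > 0.
#' @param k_base base rate constant at zero concentration (s^-1).
#' @return Rate constant (s^-1).
#' @export
kapp_hyperbolic <- function(conc, k_max, K_half, k_base) {
  stopifnot(K_half > 0, all(conc >= 0))
  k_max * conc / (K_half + conc) + k_base
}

#' Fraction of effector bound at equilibrium (exact quadratic isotherm)
#'
#' Exact solution of `H + E <-> HE` mass balance at total concentrations
#' `[H]` and `[E]`, valid in the tight-binding regime where probe depletion
#' matters:
#' \deqn{f_{bound} = \frac{1}{2[E]}\left([H]+[E]+K_d -
#'   \sqrt{([H]+[E]+K_d)^2 - 4[H][E]}\right)}
#' Implemented in the algebraically equivalent rationalized form
#' `2[H] / (b + sqrt(b^2 - 4[H][E]))` with `b = [H]+[E]+K_d`, which is
#' numerically stable and returns the dilute-probe limit `[H]/([H]+K_d)`
#' continuously as `[E] -> 0` (the documented convention at `E_tot = 0`).
#'
#' @param H_tot total host concentration (M); vectorized.
#' @param E_tot total effector (probe) concentration (M).
#' @param K_d host:effector dissociation constant (M), > 0.
#' @return Fraction of effector bound, in \[0, 1\].
#' @export
fraction_bound <- function(H_tot, E_tot, K_d) {
  stopifnot(all(H_tot >= 0), all(E_tot >= 0), K_d > 0)
  b <- H_tot + E_tot + K_d
  disc <- pmax(b^2 - 4 * H_tot * E_tot, 0)
  2 * H_tot / (b + sqrt(disc))
}

#' Fluorescence polarization from parallel/perpendicular intensities
#'
#' `P = 1000 * (parallel - perpendicular) / (parallel + perpendicular)`,
#' in milli-polarization units (mP).
#'
#' @param parallel parallel fluorescence intensity, >= 0.
#' @param perpendicular perpendicular fluorescence intensity, >= 0.
#' @return Polarization in mP, in \[-1000, 1000\].
#' @export
polarization <- function(parallel, perpendicular) {
  stopifnot(all(parallel >= 0), all(perpendicular >= 0))
  tot <- parallel + perpendicular
  if (any(tot <= 0))
    stop("polarization undefined: parallel + perpendicular must be > 0",
         call. = FALSE)
  1000 * (parallel - perpendicular) / tot
}
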