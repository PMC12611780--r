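# Multi-cycle SPR chip model: ternary-complex kinetics on the chip with
# accumulation of an effector-unresponsive host population (THn).
#
# Within one dissociation phase (constant [E] under flow) the system
#   d[THE]/dt = -k_off_T_HE [THE] + k_on_TH_E [TH][E] - k_off_TH_E [THE]
#   d[TH]/dt  = -k_off_T_H [TH] - k_on_TH_E [TH][E] + k_off_TH_E [THE]
#   d[THn]/dt = -k_off_T_Hn [THn]
# is linear, so the per-cycle solution is computed in closed form from the
# eigen-decomposition of the 2x2 ([THE],[TH]) block; THn decays separately.
# The synthetic-data generator integrates the same equations numerically
# (deSolve) so round-trip tests exercise two independent solvers.

.chip_param_names <- c("k_off_T_H", "k_off_T_HE", "k_on_TH_E", "k_off_TH_E",
                       "k_off_T_Hn")

#' Right-hand side of the chip ODE system
#'
#' @param state named numeric vector with elements `THE`, `TH`, `THn`
#'   (dimensionless chip fractions).
#' @param E_conc effector concentration (M), constant within a phase.
#' @param params named list/vector with `k_off_T_H`, `k_off_T_HE`,
#'   `k_on_TH_E`, `k_off_TH_E`, `k_off_T_Hn`.
#' @return Named derivative vector d(state)/dt.
#' @export
chip_ode_rhs <- function(state, E_conc, params) {
  stopifnot(E_conc >= 0)
  THE <- state[["THE"]]; TH <- state[["TH"]]; THn <- state[["THn"]]
  p <- as.list(params)
  bind <- p$k_on_TH_E * TH * E_conc
  c(THE = -p$k_off_T_HE * THE + bind - p$k_off_TH_E * THE,
    TH  = -p$k_off_T_H * TH - bind + p$k_off_TH_E * THE,
    THn = -p$k_off_T_Hn * THn)
}

# eigen-decomposition of the 2x2 ([THE],[TH]) block at effector
# concentration E; eigenvalues are always real (the discriminant is a sum
# of squares plus a non-negative cross term)
.chip_eigen <- function(E, params) {
  p <- as.list(params)
  a <- p$k_off_T_HE; cc <- p$k_off_TH_E; b <- p$k_on_TH_E * E
  d <- p$k_off_T_H
  tr <- -(a + cc) - (d + b)
  det <- (a + cc) * (d + b) - b * cc
  disc <- max(tr^2 - 4 * det, 0)
  lam <- c((tr + sqrt(disc)) / 2, (tr - sqrt(disc)) / 2)
  list(a = a, cc = cc, b = b, d = d, lam = lam)
}

# closed-form propagation of (THE, TH, THn) over `times` (starting at 0)
.chip_propagate <- function(state0, E, params, times) {
  eg <- .chip_eigen(E, params)
  THE0 <- state0[["THE"]]; TH0 <- state0[["TH"]]; THn0 <- state0[["THn"]]
  p <- as.list(params)
  if (eg$b == 0) {
    # no effector flux: THE feeds TH at k_off_TH_E while decaying
    kTHE <- eg$a + eg$cc
    THE <- THE0 * exp(-kTHE * times)
    if (THE0 == 0) {
      TH <- TH0 * exp(-eg$d * times)
    } else if (abs(eg$d - kTHE) < 1e-12 * max(eg$d, kTHE, 1e-300)) {
      TH <- (TH0 + eg$cc * THE0 * times) * exp(-eg$d * times)
    } else {
      TH <- TH0 * exp(-eg$d * times) +
        eg$cc * THE0 * (exp(-kTHE * times) - exp(-eg$d * times)) /
        (eg$d - kTHE)
    }
  } else {
    # eigenvector for lambda_i is (b, (a+cc) + lambda_i)
    v1 <- eg$a + eg$cc + eg$lam[1]
    v2 <- eg$a + eg$cc + eg$lam[2]
    detV <- eg$b * (v2 - v1)
    if (abs(detV) < 1e-300) {
      # degenerate eigenvalues: fall back to numeric integration
      return(.chip_propagate_ode(state0, E, params, times))
    }
    c1 <- (v2 * THE0 - eg$b * TH0) / detV
    c2 <- (-v1 * THE0 + eg$b * TH0) / detV
    e1 <- exp(eg$lam[1] * times); e2 <- exp(eg$lam[2] * times)
    THE <- eg$b * (c1 * e1 + c2 * e2)
    TH <- v1 * c1 * e1 + v2 * c2 * e2
  }
  THn <- THn0 * exp(-p$k_off_T_Hn * times)
  cbind(THE = THE, TH = TH, THn = THn)
}

# numerical route used by the generator and as degenerate-case fallback
.chip_propagate_ode <- function(state0, E, params, times) {
  y0 <- c(THE = state0[["THE"]], TH = state0[["TH"]], THn = state0[["THn"]])
  rhs <- function(t, y, parms) list(chip_ode_rhs(y, E, params))
  tt <- times
  add0 <- tt[1] > 0
  if (add0) tt <- c(0, tt)
  out <- deSolve::ode(y0, tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-14)
  res <- out[, c("THE", "TH", "THn"), drop = FALSE]
  if (add0) res <- res[-1, , drop = FALSE]
  res
}

#' Propagate chip states across ordered SPR cycles
#'
#' Applies the multi-cycle initial-value recursion: each cycle starts with
#' `[THE] = 0`; the responsive fraction of free capture sites left by the
#' previous cycle is reloaded into `[TH]` and the rest accumulates as
#' unresponsive `[THn]`:
#' `[TH]_init,n  = [TH]_final,n-1  + f_responsive * [T]_final,n-1`,
#' `[THn]_init,n = [THn]_final,n-1 + (1 - f_responsive) * [T]_final,n-1`,
#' with `[T]_final = 1 - [TH]_final - [THn]_final` and zero initial
#' occupancy before the first cycle. Association phases are summarized by
#' this end-state reloading; only dissociation phases are integrated.
#'
#' @param cycle_defs list with one element per cycle, each a list with
#'   `E` (effector concentration, M) and `times` (dissociation sample
#'   times from phase start, s; the last time is the phase duration).
#' @param params chip parameters: the five rate constants plus
#'   `f_responsive`.
#' @param engine `"analytic"` (closed form) or `"ode"` (deSolve).
#' @return List with `initial` and `final` state matrices (cycle rows) and
#'   `trajectories` (list of per-cycle state matrices over `times`).
#' @export
propagate_cycles <- function(cycle_defs, params, engine = c("analytic", "ode")) {
  engine <- match.arg(engine)
  prop <- if (engine == "analytic") .chip_propagate else .chip_propagate_ode
  f_resp <- params[["f_responsive"]]
  stopifnot(f_resp >= 0, f_resp <= 1)
  n <- length(cycle_defs)
  init <- final <- matrix(NA_real_, n, 3,
                          dimnames = list(NULL, c("THE", "TH", "THn")))
  trajectories <- vector("list", n)
  TH_f <- 0; THn_f <- 0
  for (i in seq_len(n)) {
    T_f <- 1 - TH_f - THn_f
    s0 <- c(THE = 0, TH = TH_f + f_resp * T_f,
            THn = THn_f + (1 - f_resp) * T_f)
    init[i, ] <- s0
    tt <- cycle_defs[[i]]$times
    traj <- prop(s0, cycle_defs[[i]]$E, params, tt)
    trajectories[[i]] <- traj
    fin <- traj[nrow(traj), ]
    final[i, ] <- fin
    TH_f <- fin[["TH"]]; THn_f <- fin[["THn"]]
  }
  list(initial = init, final = final, trajectories = trajectories)
}

#' Map chip-state trajectories to an SPR response
#'
#' `S = f_n * (a_TH [TH] + a_THE [THE] + a_THn [THn])`: a linear read-out
#' with per-state amplitudes and a per-cycle amplitude factor; no baseline
#' term (baselines are handled upstream).
#'
#' @param traj state matrix with columns `THE`, `TH`, `THn`.
#' @param amplitudes named vector/list with `a_TH`, `a_THE`, `a_THn`
#'   (response per unit chip fraction, >= 0).
#' @param f_n per-cycle amplitude factor.
#' @return Numeric response vector.
#' @export
response_model <- function(traj, amplitudes, f_n = 1) {
  a <- as.list(amplitudes)
  stopifnot(a$a_TH >= 0, a$a_THE >= 0, a$a_THn >= 0)
  f_n * (a$a_TH * traj[, "TH"] + a$a_THE * traj[, "THE"] +
           a$a_THn * traj[, "THn"])
}

# split a cycle_set data frame into the per-cycle structures used by the
# model (dissociation phases only, times re-zeroed to phase start)
.cycles_to_defs <- function(cycles) {
  df <- as.data.frame(cycles)
  df <- df[df$phase == "dissociation", ]
  ids <- sort(unique(df$cycle))
  lapply(ids, function(i) {
    d <- df[df$cycle == i, ]
    d <- d[order(d$time_s), ]
    list(cycle = i, E = d$effector_conc_M[1],
         times = d$time_s - d$time_s[1], response = d$signal %||% d$response)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# predicted responses for all cycles, concatenated in cycle order
.predict_cycles <- function(defs, params, amplitudes, f_n,
                            engine = "analytic") {
  pc <- propagate_cycles(defs, params, engine = engine)
  unlist(lapply(seq_along(defs), function(i)
    response_model(pc$trajectories[[i]], amplitudes, f_n[i])))
}
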