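# Synthetic-assay generators with known ground truth. These emulate the
# study's assay regimes (multi-cycle SPR with host capture and a twofold
# effector dilution series, FP titrations obeying the exact quadratic
# isotherm, exponential competition/transfer time courses with an optional
# sigmoid baseline drift) so every fitting stage can be validated by
# parameter recovery.

# run code with a local, restored RNG state; a fixed seed gives
# byte-identical output
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Additive noise model
#'
#' Additive Gaussian noise, specified either as an absolute standard
#' deviation (`sigma`, signal units) or as a fraction of the full-scale
#' amplitude (`sigma_frac`). Default: 0.5% of full scale. A fixed seed
#' makes the generated dataset byte-identical across calls.
#'
#' @param sigma absolute standard deviation (signal units), or `NULL` to
#'   use `sigma_frac`.
#' @param sigma_frac fractional standard deviation of full scale.
#' @param seed integer RNG seed (mandatory for reproducible datasets).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma = NULL, sigma_frac = 0.005, seed = 1L) {
  stopifnot(is.null(sigma) || sigma >= 0, sigma_frac >= 0)
  structure(list(sigma = sigma, sigma_frac = sigma_frac,
                 seed = as.integer(seed)),
            class = "noise_model")
}

.noise_sigma <- function(noise, full_scale) {
  if (!is.null(noise$sigma)) noise$sigma else noise$sigma_frac * full_scale
}

#' Multi-cycle SPR experiment design
#'
#' The effector concentration series is a twofold serial dilution from
#' `E_top`; by default an effector-free cycle precedes the series, so the
#' base target off-rate is measured under zero effector as in the SPR
#' protocol. Dissociation phases default to 2 h sampled at 1 Hz.
#'
#' @param E_top top effector concentration (M).
#' @param n_conc number of non-zero effector concentrations.
#' @param fold_step dilution factor between consecutive cycles.
#' @param include_zero prepend an effector-free cycle.
#' @param t_diss dissociation phase duration (s).
#' @param dt sampling interval (s).
#' @param t_assoc association (host reloading) duration (s), metadata only:
#'   association phases are summarized by their end state.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(E_top = 5e-6, n_conc = 8, fold_step = 2,
                              include_zero = TRUE, t_diss = 7200, dt = 1,
                              t_assoc = 60) {
  stopifnot(E_top > 0, n_conc >= 1, fold_step > 1, t_diss > 0, dt > 0)
  E_series <- E_top / fold_step^((n_conc - 1):0)   # ascending
  if (include_zero) E_series <- c(0, E_series)
  structure(list(E_top = E_top, n_conc = n_conc, fold_step = fold_step,
                 include_zero = include_zero, E_series = E_series,
                 t_diss = t_diss, dt = dt, t_assoc = t_assoc),
            class = "experiment_design")
}

#' Generate a synthetic multi-cycle SPR cycle set
#'
#' Forward-simulates the chip model (numerical integration of the chip
#' ODEs) with the multi-cycle reloading recursion, maps states to a
#' response with per-state amplitudes and per-cycle factors, and adds
#' Gaussian noise. Ground truth is embedded in the `truth` attribute for
#' recovery scoring.
#'
#' A coverage warning is attached when the dissociation phase does not
#' span at least three half-lives of the fastest effective rate (the rate
#' at the top effector concentration).
#'
#' @param params named list: the five chip rate constants, `f_responsive`,
#'   and optionally amplitudes `a_TH`, `a_THE`, `a_THn` (default 1) and a
#'   per-cycle factor vector `f_n` (default: `f_1 = 1`, later cycles
#'   jittered by `f_n_jitter`).
#' @param design an [experiment_design()].
#' @param noise a [noise_model()].
#' @param f_n_jitter lognormal-ish sd of the per-cycle amplitude factors
#'   emulating small cycle-to-cycle amplitude differences.
#' @return Object of class `cycle_set`: a data frame with columns
#'   `time_s`, `response`, `cycle`, `phase`, `effector_conc_M`, with
#'   attributes `truth` and `design`.
#' @export
gen_cycleset <- function(params, design = experiment_design(),
                         noise = noise_model(), f_n_jitter = 0.02) {
  p <- params
  for (nm in c("a_TH", "a_THE", "a_THn")) if (is.null(p[[nm]])) p[[nm]] <- 1
  need <- c(.chip_param_names, "f_responsive")
  miss <- need[!need %in% names(p)]
  if (length(miss))
    stop("missing chip parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)

  n_cyc <- length(design$E_series)
  times <- seq(0, design$t_diss, by = design$dt)
  defs <- lapply(design$E_series, function(E) list(E = E, times = times))

  .with_seed(noise$seed, {
    f_n <- p$f_n
    if (is.null(f_n)) {
      f_n <- c(1, 1 + stats::rnorm(n_cyc - 1, 0, f_n_jitter))
      f_n <- pmax(f_n, 0.5)
    }
    rates <- unlist(p[.chip_param_names])
    pc <- propagate_cycles(defs, c(rates, f_responsive = p$f_responsive),
                           engine = "ode")
    amps <- c(a_TH = p$a_TH, a_THE = p$a_THE, a_THn = p$a_THn)
    clean <- lapply(seq_len(n_cyc), function(i)
      response_model(pc$trajectories[[i]], amps, f_n[i]))
    full_scale <- max(unlist(clean))
    sigma <- .noise_sigma(noise, full_scale)
    df <- do.call(rbind, lapply(seq_len(n_cyc), function(i) {
      y <- clean[[i]]
      if (sigma > 0) y <- y + stats::rnorm(length(y), 0, sigma)
      data.frame(time_s = times, response = y, cycle = i,
                 phase = "dissociation",
                 effector_conc_M = design$E_series[i])
    }))
    truth <- c(as.list(rates), list(f_responsive = p$f_responsive,
                                    a_TH = p$a_TH, a_THE = p$a_THE,
                                    a_THn = p$a_THn, f_n = f_n,
                                    sigma = sigma, seed = noise$seed))
    k_fast <- compute_keff(rates, design$E_top)
    if (design$t_diss < 3 * log(2) / k_fast)
      warning("coverage: dissociation phase shorter than 3 half-lives at ",
              "the fastest effective rate (", format(k_fast), " s^-1)",
              call. = FALSE)
    structure(df, truth = truth, design = design,
              class = c("cycle_set", "data.frame"))
  })
}

#' Generate a synthetic fluorescence-polarization titration
#'
#' Host titrated by serial dilution across a constant labelled-effector
#' probe; polarization follows the exact quadratic isotherm
#' `P = P0 + P1 * f_bound`.
#'
#' @param K_d host:effector dissociation constant (M).
#' @param probe_conc labelled-effector concentration (M).
#' @param P0 free-probe polarization (mP).
#' @param P1 polarization change on binding (mP).
#' @param top_conc top host concentration (M).
#' @param n_points number of titration points (twofold series), default 24.
#' @param fold_step dilution factor.
#' @param noise a [noise_model()]; sigma fraction applies to `|P1|`.
#' @return Data frame with `host_conc_M` and `polarization_mP`, with a
#'   `truth` attribute.
#' @export
gen_fp_titration <- function(K_d, probe_conc, P0 = 50, P1 = 150,
                             top_conc = 1e-6, n_points = 24, fold_step = 2,
                             noise = noise_model()) {
  H <- c(0, top_conc / fold_step^((n_points - 2):0))
  P <- P0 + P1 * fraction_bound(H, probe_conc, K_d)
  sigma <- .noise_sigma(noise, abs(P1))
  .with_seed(noise$seed, {
    if (sigma > 0) P <- P + stats::rnorm(length(P), 0, sigma)
    structure(data.frame(host_conc_M = H, polarization_mP = P),
              truth = list(K_d = K_d, probe_conc = probe_conc, P0 = P0,
                           P1 = P1, sigma = sigma, seed = noise$seed))
  })
}

#' Generate synthetic competition / transfer / luminescence time courses
#'
#' Exponential time courses for the solution-phase assays:
#'
#' * `"forward"`: kinetic competition rises
#'   `P0 + P1 (1 - exp(-k_app t))`, one course per supplied `k_app`.
#' * `"reverse"`: reverse facilitated dissociation decays at rates given by
#'   the hyperbolic law `k_off_TH_E [T] / (K_half + [T]) + k_off_HE` over a
#'   target-concentration series including a zero-target baseline.
#' * `"chain"`: FRET transfer decay plus an optional sigmoid baseline
#'   drift; a drift-only reference course (zero amplitude) is included.
#' * `"luminescence"`: sensor activation rise (or split-enzyme breakage
#'   decay) at rate `ln(2) / half_time`.
#'
#' @param kind assay kind, see above.
#' @param params named list of ground-truth parameters; see details of
#'   each kind in the source. Common: `S0`, `S1` (signal baseline and
#'   amplitude).
#' @param t_max course duration (s); default covers 5 half-lives of the
#'   slowest rate.
#' @param dt sampling interval (s), default 1.
#' @param noise a [noise_model()].
#' @param drift optional sigmoid drift parameters
#'   (`S0`, `S1`, `k`, `t_half`) for `kind = "chain"`.
#' @return List of [time_course()] objects with a `truth` attribute.
#' @export
gen_competition_courses <- function(kind = c("forward", "reverse", "chain",
                                             "luminescence"),
                                    params, t_max = NULL, dt = 1,
                                    noise = noise_model(), drift = NULL) {
  kind <- match.arg(kind)
  p <- params
  S0 <- p$S0 %||% 0
  S1 <- p$S1 %||% 1

  courses <- switch(kind,
    forward = {
      ks <- p$k_app
      if (is.null(t_max)) t_max <- 5 * log(2) / min(ks)
      tt <- seq(0, t_max, by = dt)
      lapply(seq_along(ks), function(i)
        time_course(tt, S0 + S1 * (1 - exp(-ks[i] * tt)), assay = "fp",
                    conc = (p$conc %||% rep(NA_real_, length(ks)))[i],
                    phase = "association"))
    },
    reverse = {
      Tconc <- p$T_conc
      ks <- kapp_hyperbolic(Tconc, p$k_off_TH_E, p$K_half, p$k_off_HE)
      if (is.null(t_max)) t_max <- 5 * log(2) / min(ks)
      tt <- seq(0, t_max, by = dt)
      lapply(seq_along(Tconc), function(i)
        time_course(tt, S0 + S1 * exp(-ks[i] * tt), assay = "fp",
                    conc = Tconc[i], phase = "dissociation"))
    },
    chain = {
      k <- p$k_app
      if (is.null(t_max)) t_max <- 5 * log(2) / k
      tt <- seq(0, t_max, by = dt)
      dr <- if (is.null(drift)) rep(0, length(tt)) else
        drift$S0 + drift$S1 / (1 + exp(-drift$k * (tt - drift$t_half)))
      list(
        time_course(tt, S0 + S1 * exp(-k * tt) + dr, assay = "fret",
                    conc = p$conc %||% NA_real_, phase = "dissociation"),
        time_course(tt, dr, assay = "fret", conc = 0, phase = "reference")
      )
    },
    luminescence = {
      k <- log(2) / p$half_time
      direction <- p$direction %||% "rise"
      if (is.null(t_max)) t_max <- 10 * p$half_time
      tt <- seq(0, t_max, by = dt)
      y <- if (direction == "rise") S0 + S1 * (1 - exp(-k * tt)) else
        S0 + S1 * exp(-k * tt)
      list(time_course(tt, y, assay = "luminescence",
                       conc = p$conc %||% NA_real_, phase = direction))
    })

  sigma <- .noise_sigma(noise, abs(S1))
  .with_seed(noise$seed, {
    if (sigma > 0)
      courses <- lapply(courses, function(tc) {
        tc$signal <- tc$signal + stats::rnorm(length(tc$signal), 0, sigma)
        tc
      })
    structure(courses, truth = c(p, list(sigma = sigma, seed = noise$seed,
                                         drift = drift)))
  })
}

#' Write / read a cycle set with its ground-truth manifest
#'
#' The cycle set is written as CSV (columns `time_s`, `response`, `cycle`,
#' `phase`, `effector_conc_M`); ground truth and design go to a JSON
#' manifest so metadata round-trips losslessly.
#'
#' @param cs a `cycle_set`.
#' @param csv_path,json_path file paths.
#' @return `write_cycleset` returns `csv_path` invisibly; `read_cycleset`
#'   returns the reconstructed `cycle_set`.
#' @export
write_cycleset <- function(cs, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(cs), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    tr <- attr(cs, "truth")
    de <- attr(cs, "design")
    jsonlite::write_json(
      list(schema = "fdkin/cycle_set", schema_version = 1L,
           truth = tr, design = unclass(de)),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(csv_path)
}

#' @rdname write_cycleset
#' @export
read_cycleset <- function(csv_path, json_path = NULL) {
  df <- utils::read.csv(csv_path)
  truth <- design <- NULL
  if (!is.null(json_path)) {
    m <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    truth <- m$truth
    design <- m$design
    if (!is.null(design)) class(design) <- "experiment_design"
  }
  structure(df, truth = truth, design = design,
            class = c("cycle_set", "data.frame"))
}
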