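# Pipeline stages tying the fitting machinery into reproducible runs:
# forward/reverse characterization reports, the parameter-recovery harness
# and a JSON run-configuration reader. The numbered scripts under
# analysis/ are thin drivers over these functions.

#' Characterize forward facilitated dissociation from a cycle set
#'
#' Runs the global multi-cycle fit, extracts the effective-rate curve and
#' the constrained hyperbolic summary, and assembles one report: fitted
#' rate constants, unresponsive fraction, fold acceleration, K_1/2 and
#' per-cycle residuals.
#'
#' @param cycles a `cycle_set` (or data frame in the cycle-set CSV
#'   dialect).
#' @param E_grid optional effector grid for the k_eff curve.
#' @param init optional initial values passed to [global_fit()].
#' @return A report list; write it with [write_report_json()].
#' @export
characterize_forward <- function(cycles, E_grid = NULL, init = NULL) {
  gf <- global_fit(cycles, init = init)
  fd <- summarize_fd(gf$params, E_grid = E_grid)
  list(kind = "characterize_forward",
       package_version = as.character(utils::packageVersion("fdkin")),
       params = as.list(gf$params),
       amplitudes = as.list(gf$amplitudes),
       f_n = gf$f_n,
       fold_acceleration = fd$fold_acceleration,
       K_half = fd$K_half,
       k_eff = fd$k_eff,
       cycle_rms = gf$cycle_rms,
       rms = gf$rms,
       identifiability = gf$identifiability)
}

#' Characterize reverse facilitated dissociation from time courses
#'
#' Per-course exponential fits followed by the hyperbolic fit of the
#' apparent effector off-rate versus target concentration; the fold
#' acceleration is `(k_off_TH_E + k_off_HE) / k_off_HE` evaluated from the
#' accelerated and base effector off-rates.
#'
#' @param courses list of [time_course()] objects (see [fit_reverse_fd()]).
#' @return A report list.
#' @export
characterize_reverse <- function(courses) {
  dr <- fit_reverse_fd(courses)
  p <- dr$params
  list(kind = "characterize_reverse",
       package_version = as.character(utils::packageVersion("fdkin")),
       params = as.list(p),
       fold_acceleration = unname((p[["k_off_TH_E"]] + p[["k_off_HE"]]) /
                                    p[["k_off_HE"]]),
       K_half = unname(p[["K_half"]]),
       k_app = data.frame(target_conc_M = dr$conc, k_app = dr$kapp),
       rms = dr$rms)
}

#' Parameter-recovery harness for the global SPR fit
#'
#' Draws random ground-truth parameter sets (log-uniform over the stated
#' ranges), generates a synthetic cycle set for each, refits globally and
#' scores the relative recovery error of the key parameters.
#'
#' @param n_sets number of random parameter sets.
#' @param seed RNG seed controlling both the draws and the noise.
#' @param noise_frac noise sigma as a fraction of full scale.
#' @param design an [experiment_design()]; the default reduced sampling
#'   (10 s interval) keeps a sweep fast without degrading recovery.
#' @param ranges named list of `c(min, max)` ranges for `k_off_T_H`, the
#'   fold acceleration, `k_on_TH_E` and `f_responsive`.
#' @return Data frame with truth, estimates and relative errors per set.
#' @export
recover_sweep <- function(n_sets = 20, seed = 1L, noise_frac = 0.005,
                          design = experiment_design(dt = 10),
                          ranges = list(k_off_T_H = c(1e-5, 1e-4),
                                        fold = c(50, 5000),
                                        k_on_TH_E = c(1e4, 1e6),
                                        f_responsive = c(0.8, 0.98))) {
  draw <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  rows <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    truth <- .with_seed(seed + i, list(
      k_off_T_H = draw(ranges$k_off_T_H[1], ranges$k_off_T_H[2]),
      fold = draw(ranges$fold[1], ranges$fold[2]),
      k_on_TH_E = draw(ranges$k_on_TH_E[1], ranges$k_on_TH_E[2]),
      f_responsive = stats::runif(1, ranges$f_responsive[1],
                                  ranges$f_responsive[2])))
    params <- list(k_off_T_H = truth$k_off_T_H,
                   k_off_T_HE = truth$k_off_T_H * truth$fold,
                   k_on_TH_E = truth$k_on_TH_E, k_off_TH_E = 1e-4,
                   k_off_T_Hn = truth$k_off_T_H,
                   f_responsive = truth$f_responsive)
    cs <- suppressWarnings(gen_cycleset(
      params, design = design,
      noise = noise_model(sigma_frac = noise_frac, seed = seed * 1000 + i)))
    gf <- suppressWarnings(global_fit(cs))
    est <- gf$params
    rows[[i]] <- data.frame(
      set = i,
      k_off_T_H_true = params$k_off_T_H,
      k_off_T_H_est = est[["k_off_T_H"]],
      k_off_T_HE_true = params$k_off_T_HE,
      k_off_T_HE_est = est[["k_off_T_HE"]],
      f_responsive_true = params$f_responsive,
      f_responsive_est = est[["f_responsive"]])
  }
  out <- do.call(rbind, rows)
  out$rel_err_k_off_T_H <- abs(out$k_off_T_H_est / out$k_off_T_H_true - 1)
  out$rel_err_k_off_T_HE <- abs(out$k_off_T_HE_est / out$k_off_T_HE_true - 1)
  out$rel_err_f_responsive <-
    abs(out$f_responsive_est / out$f_responsive_true - 1)
  out
}

#' Read a run configuration from JSON
#'
#' A run's configuration plus its inputs determine its outputs; the
#' configuration hash is embedded in reports for provenance.
#'
#' @param path JSON file path.
#' @return List with the configuration values, defaults filled in, and a
#'   `config_hash` (md5 of the canonicalized JSON).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(assay = "spr_multicycle", law = "hyperbolic",
                   topology = "induced_fit", seed = 1L,
                   output_dir = ".")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  cfg$config_hash <- unname(tools::md5sum(tmp))
  cfg
}

#' Write a report list as JSON
#'
#' @param report a report list from [characterize_forward()] or
#'   [characterize_reverse()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
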