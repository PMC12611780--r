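# Dose-response law fitting: linear, hyperbolic and conformational-selection
# apparent-rate laws, the FP binding isotherm, reverse facilitated
# dissociation, and sigmoid baseline-drift subtraction.

#' Fit a rate law to a (concentration, apparent rate) series
#'
#' Laws:
#' * `"linear"`: `k_app = k_on * c + k_off` (ordinary least squares).
#' * `"hyperbolic"`: `k_app = k_max * c / (K_half + c) + k_base`
#'   (Levenberg-Marquardt, rates in log-space, `k_base >= 0`). Supplying
#'   `fix = list(k_max =, k_base =)` performs the constrained fit with only
#'   `K_half` free.
#' * `"conformational_selection"`: the slow-relaxation law
#'   [kapp_conformational_selection()], with `k_off` box-bounded below
#'   1e-4 s^-1 as observed for the slowly dissociating ternary complex.
#'
#' A warning (not a failure) is attached when saturation is not approached,
#' i.e. the largest concentration is below the fitted half-saturation
#' constant.
#'
#' @param conc concentrations (M), distinct; at least one more point than
#'   the law's parameter count.
#' @param kapp apparent rate constants (s^-1).
#' @param law one of `"linear"`, `"hyperbolic"`,
#'   `"conformational_selection"`.
#' @param fix optional named list of parameters to hold fixed
#'   (hyperbolic law only: `k_max` and `k_base`).
#' @param weights optional non-negative case weights for the least-squares
#'   objective. Rate constants estimated from exponential fits carry
#'   roughly proportional errors, so `1/kapp^2` weighting (relative least
#'   squares) is appropriate when a series spans decades.
#' @return Object of class `dose_response`: the data, the law, named
#'   `params`, `cov`, `fitted`, residual `rms` (unweighted), the weighted
#'   residual sum of squares `wrss`, and any `warnings`.
#' @export
fit_dose_response <- function(conc, kapp,
                              law = c("linear", "hyperbolic",
                                      "conformational_selection"),
                              fix = NULL, weights = NULL) {
  law <- match.arg(law)
  stopifnot(length(conc) == length(kapp), all(conc >= 0))
  if (anyDuplicated(conc))
    stop("concentrations must be distinct", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(conc))
  stopifnot(length(weights) == length(conc), all(weights >= 0))
  npar <- switch(law, linear = 2L, hyperbolic = 3L,
                 conformational_selection = 4L)
  nfree <- npar - length(fix)
  if (length(conc) < nfree + 1)
    stop("need at least ", nfree + 1, " concentrations for the ", law,
         " law", call. = FALSE)
  warnings <- character(0)

  if (law == "linear") {
    lmfit <- stats::lm(kapp ~ conc, weights = weights)
    params <- c(k_on = unname(stats::coef(lmfit)[2]),
                k_off = unname(stats::coef(lmfit)[1]))
    cov <- suppressWarnings(stats::vcov(lmfit))
    dimnames(cov) <- list(c("k_off", "k_on"), c("k_off", "k_on"))
    fitted <- unname(stats::fitted(lmfit))
    rss <- sum(stats::residuals(lmfit)^2)
  } else if (law == "hyperbolic") {
    hyp <- .fit_hyperbolic(conc, kapp, fix, weights)
    params <- hyp$params; cov <- hyp$cov; fitted <- hyp$fitted
    rss <- hyp$rss
    if (max(conc) < params[["K_half"]])
      warnings <- c(warnings, paste0(
        "saturation not approached: max concentration ", format(max(conc)),
        " M is below fitted K_half ", format(params[["K_half"]]),
        " M; K_half has a wide confidence interval"))
  } else {
    cs <- .fit_cs_law(conc, kapp, weights)
    params <- cs$params; cov <- cs$cov; fitted <- cs$fitted; rss <- cs$rss
    half <- (params[["k_switch"]] + params[["k_unswitch"]]) /
      max(params[["k_on"]], .Machine$double.xmin)
    if (max(conc) < half)
      warnings <- c(warnings,
        "saturation not approached: k_switch has a wide confidence interval")
  }
  for (w in warnings) warning(w, call. = FALSE)
  structure(list(conc = conc, kapp = kapp, law = law, params = params,
                 cov = cov, fitted = fitted,
                 rms = sqrt(mean((fitted - kapp)^2)),
                 wrss = sum(weights * (fitted - kapp)^2),
                 warnings = warnings),
            class = "dose_response")
}

.fit_hyperbolic <- function(conc, kapp, fix = NULL,
                            weights = rep(1, length(conc))) {
  sw <- sqrt(weights)
  cpos <- conc[conc > 0]
  kh_grid <- if (length(cpos)) {
    exp(seq(log(min(cpos) / 4), log(max(cpos) * 4), length.out = 7))
  } else 1e-6
  if (!is.null(fix)) {
    stopifnot(all(c("k_max", "k_base") %in% names(fix)))
    obj <- function(lkh) sum(weights * (kapp_hyperbolic(conc, fix$k_max,
                                                        exp(lkh),
                                                        fix$k_base) - kapp)^2)
    vals <- vapply(log(kh_grid), obj, numeric(1))
    lo <- log(min(kh_grid)) - 6; hi <- log(max(kh_grid)) + 6
    opt <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
    if (min(vals) < opt$objective)
      opt <- stats::optimize(obj, log(kh_grid[which.min(vals)]) + c(-1, 1),
                             tol = 1e-12)
    K_half <- exp(opt$minimum)
    params <- c(k_max = fix$k_max, K_half = K_half, k_base = fix$k_base)
    fitted <- kapp_hyperbolic(conc, fix$k_max, K_half, fix$k_base)
    rss <- sum((fitted - kapp)^2)
    # 1-D curvature-based variance on log K_half
    h <- 1e-4
    d2 <- (obj(opt$minimum + h) - 2 * rss + obj(opt$minimum - h)) / h^2
    vlog <- if (d2 > 0) 2 * rss / max(length(conc) - 1, 1) / d2 else NA_real_
    cov <- matrix(vlog * K_half^2, 1, 1,
                  dimnames = list("K_half", "K_half"))
    return(list(params = params, cov = cov, fitted = fitted, rss = rss))
  }
  k_base0 <- max(min(kapp), 0)
  k_max0 <- max(max(kapp) - k_base0, 1e-12)
  resid <- function(p) {
    sw * (kapp_hyperbolic(conc, exp(p[1]), exp(p[2]), p[3]) - kapp)
  }
  best <- NULL
  for (kh0 in kh_grid) {
    p0 <- c(log(k_max0), log(kh0), k_base0)
    fit <- try(minpack.lm::nls.lm(p0, fn = resid,
                                  lower = c(-Inf, -Inf, 0),
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500, ftol = 1e-15,
                                    ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("hyperbolic fit did not converge", call. = FALSE)
  p <- best$par
  params <- c(k_max = exp(p[1]), K_half = exp(p[2]), k_base = p[3])
  fitted <- kapp_hyperbolic(conc, params[1], params[2], params[3])
  rss <- best$deviance
  cov <- .lm_cov(best, length(conc))
  # delta-method back to natural scale for the log-parameterized entries
  scale <- c(params[1], params[2], 1)
  cov <- cov * tcrossprod(scale)
  dimnames(cov) <- list(names(params), names(params))
  list(params = params, cov = cov, fitted = fitted, rss = rss)
}

.fit_cs_law <- function(conc, kapp, weights = rep(1, length(conc))) {
  sw <- sqrt(weights)
  ks0 <- max(kapp)
  koff0 <- max(min(min(kapp) / 2, 5e-5), 1e-9)
  resid <- function(p) {
    sw * (kapp_conformational_selection(conc, exp(p[1]), exp(p[2]),
                                        exp(p[3]), exp(p[4])) - kapp)
  }
  cmid <- stats::median(conc[conc > 0])
  best <- NULL
  for (mult in c(3, 10, 30, 100)) {
    ku0 <- mult * ks0
    kon0 <- (ks0 + ku0) / cmid
    p0 <- log(c(ks0, ku0, kon0, koff0))
    fit <- try(minpack.lm::nls.lm(p0, fn = resid,
                                  upper = c(Inf, Inf, Inf, log(1e-4)),
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500, ftol = 1e-15,
                                    ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("conformational-selection law fit did not converge", call. = FALSE)
  p <- exp(best$par)
  params <- c(k_switch = p[1], k_unswitch = p[2], k_on = p[3], k_off = p[4])
  fitted <- kapp_conformational_selection(conc, p[1], p[2], p[3], p[4])
  cov <- .lm_cov(best, length(conc)) * tcrossprod(p)
  dimnames(cov) <- list(names(params), names(params))
  list(params = params, cov = cov, fitted = fitted, rss = best$deviance)
}

# Jacobian-based covariance from an nls.lm fit (on the searched scale)
.lm_cov <- function(fit, n) {
  p <- length(fit$par)
  sigma2 <- fit$deviance / max(n - p, 1)
  cv <- try(solve(fit$hessian) * sigma2, silent = TRUE)
  if (inherits(cv, "try-error")) cv <- matrix(NA_real_, p, p)
  cv
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose_response (%s law, %d concentrations)\n", x$law,
              length(x$conc)))
  for (nm in names(x$params))
    cat(sprintf("  %-12s %g\n", nm, x$params[[nm]]))
  cat(sprintf("  residual RMS = %g s^-1\n", x$rms))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n   ")
  invisible(x)
}

#' Fit the FP binding isotherm to a host titration
#'
#' Fits `P = P0 + P1 * f_bound([H], [E], K_d)` with the exact quadratic
#' [fraction_bound()]. `K_d` is profiled in log-space (P0 and P1 are linear
#' and solved exactly at each candidate). When the fitted `K_d` falls below
#' the probe concentration the affinity is too strong to be resolved by the
#' titration, so the result is flagged `tight_binding` and only the bound
#' `K_d < [E]` is reported.
#'
#' @param H_conc host concentrations (M), at least 8, spanning the
#'   transition.
#' @param P measured polarizations (mP).
#' @param probe_conc total labelled-effector concentration (M).
#' @return Object of class `isotherm_fit` with `K_d`, `P0`, `P1`,
#'   `probe_conc`, `tight_binding`, `K_d_report`, `rms`.
#' @export
fit_isotherm <- function(H_conc, P, probe_conc) {
  stopifnot(length(H_conc) == length(P), probe_conc >= 0)
  if (length(H_conc) < 8)
    stop("at least 8 titration points are required", call. = FALSE)
  noise <- .noise_rms(P[order(H_conc)])
  if (max(P) - min(P) < 2 * noise || max(P) == min(P))
    stop("fit failure: no binding transition in the titration",
         call. = FALSE)
  obj <- function(lkd) {
    fb <- fraction_bound(H_conc, probe_conc, exp(lkd))
    sum(stats::lm.fit(cbind(1, fb), P)$residuals^2)
  }
  hpos <- H_conc[H_conc > 0]
  lo <- log(min(hpos)) - log(1e3); hi <- log(max(hpos)) + log(1e3)
  grid <- seq(lo, hi, length.out = 41)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  opt <- stats::optimize(obj, grid[c(max(i - 1, 1), min(i + 1, 41))],
                         tol = 1e-12)
  K_d <- exp(opt$minimum)
  fb <- fraction_bound(H_conc, probe_conc, K_d)
  cf <- stats::lm.fit(cbind(1, fb), P)$coefficients
  rss <- obj(opt$minimum)
  tight <- K_d < probe_conc
  structure(list(K_d = K_d, P0 = unname(cf[1]), P1 = unname(cf[2]),
                 probe_conc = probe_conc, tight_binding = tight,
                 K_d_report = if (tight)
                   sprintf("K_d < %g M", probe_conc) else
                   sprintf("K_d = %g M", K_d),
                 rms = sqrt(rss / length(P))),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("FP isotherm fit:", x$K_d_report, "\n")
  cat(sprintf("  P0 = %g mP, P1 = %g mP, residual RMS = %g mP\n",
              x$P0, x$P1, x$rms))
  invisible(x)
}

#' Reverse facilitated dissociation: effector off-rate versus target
#'
#' Fits a single-exponential decay to each polarization time course
#' (labelled effector chased off the host by excess unlabelled effector, at
#' varying target concentrations), then fits the hyperbolic law
#' `k_app = k_off_TH_E * [T] / (K_half + [T]) + k_off_HE` to the apparent
#' rates. A zero-target course must be present; it measures the base
#' effector off-rate.
#'
#' @param courses list of [time_course()] objects with `conc` set to the
#'   target concentration (M); exactly one course must have `conc == 0`,
#'   and the nonzero concentrations must span at least a 16-fold range.
#' @return A `dose_response` object (hyperbolic law) whose `params` are
#'   renamed `k_off_TH_E`, `K_half`, `k_off_HE`; per-course exponential
#'   fits are attached as `course_fits`.
#' @export
fit_reverse_fd <- function(courses) {
  concs <- vapply(courses, function(tc) tc$conc, numeric(1))
  if (!any(concs == 0))
    stop("a zero-target course (base effector off-rate) is required",
         call. = FALSE)
  nz <- concs[concs > 0]
  if (max(nz) / min(nz) < 16)
    stop("target concentrations must span at least a 16-fold range",
         call. = FALSE)
  fits <- lapply(courses, fit_single_exponential, direction = "decay")
  kapp <- vapply(fits, `[[`, numeric(1), "reported_rate")
  dr <- fit_dose_response(concs, kapp, law = "hyperbolic")
  names(dr$params) <- c("k_off_TH_E", "K_half", "k_off_HE")
  dimnames(dr$cov) <- list(names(dr$params), names(dr$params))
  dr$course_fits <- fits
  dr
}

#' Fit and subtract a sigmoid baseline drift
#'
#' A drift of the form `S = S1 / (1 + exp(-k (t - t_half))) + S0` is fitted
#' to a reference (analyte-free) time course and subtracted pointwise from
#' the course of interest. If the sigmoid fit does not converge the
#' fallback is constant-baseline subtraction (mean of the reference), with
#' a warning.
#'
#' @param tc the [time_course()] to correct.
#' @param reference_tc reference course covering the same time span.
#' @return The corrected `time_course`; fitted drift parameters are
#'   attached as attribute `"drift"`.
#' @export
subtract_sigmoid_drift <- function(tc, reference_tc) {
  stopifnot(inherits(tc, "time_course"), inherits(reference_tc, "time_course"))
  if (min(reference_tc$times) > min(tc$times) + 1e-9 ||
      max(reference_tc$times) < max(tc$times) - 1e-9)
    stop("reference must cover the time span of the course", call. = FALSE)
  t <- reference_tc$times
  y <- reference_tc$signal
  span <- diff(range(t))

  sig_design <- function(p) cbind(1, 1 / (1 + exp(-exp(p[1]) * (t - p[2]))))
  obj <- function(p) sum(stats::lm.fit(sig_design(p), y)$residuals^2)
  best <- NULL
  for (th in stats::quantile(t, c(0.25, 0.5, 0.75)))
    for (k0 in c(2 / span, 20 / span)) {
      o <- try(stats::nlminb(c(log(k0), th), obj,
                             control = list(rel.tol = 1e-14)), silent = TRUE)
      if (inherits(o, "try-error") || !is.finite(o$objective)) next
      if (is.null(best) || o$objective < best$objective) best <- o
    }
  if (is.null(best)) {
    warning("sigmoid drift fit did not converge; ",
            "subtracting constant baseline", call. = FALSE)
    drift_fun <- function(tt) rep(mean(y), length(tt))
    drift <- list(kind = "constant", S0 = mean(y))
  } else {
    cf <- stats::lm.fit(sig_design(best$par), y)$coefficients
    k <- exp(best$par[1]); t_half <- best$par[2]
    S0 <- unname(cf[1]); S1 <- unname(cf[2])
    drift_fun <- function(tt) S0 + S1 / (1 + exp(-k * (tt - t_half)))
    drift <- list(kind = "sigmoid", S0 = S0, S1 = S1, k = unname(k),
                  t_half = unname(t_half))
  }
  out <- time_course(tc$times, tc$signal - drift_fun(tc$times), t0 = tc$t0,
                     assay = tc$assay, conc = tc$conc, cycle = tc$cycle,
                     phase = tc$phase)
  attr(out, "drift") <- drift
  out
}
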