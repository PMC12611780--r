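# Exponential, dose-response, isotherm, reverse-FD and drift fitting.

test_that("single-exponential fit is self-consistent and handles degenerate input", {
  k <- 1e-3
  tt <- seq(0, 5 * log(2) / k, by = 20)
  y <- 0.2 + 1.3 * exp(-k * tt)
  fit <- fit_single_exponential(time_course(tt, y))
  expect_equal(fit$k_app_1, k, tolerance = 1e-6)
  expect_equal(fit$S0, 0.2, tolerance = 1e-6)
  expect_equal(fit$S1, 1.3, tolerance = 1e-6)
  # rise direction
  fitr <- fit_single_exponential(time_course(tt, 0.2 + 1.3 * (1 - exp(-k * tt))),
                                 "rise")
  expect_equal(fitr$k_app_1, k, tolerance = 1e-6)
  # constant signal: amplitude indistinguishable from zero
  expect_error(fit_single_exponential(time_course(tt, rep(1, length(tt)))),
               "fit failure")
  # too few points
  expect_error(fit_single_exponential(time_course(1:5, exp(-(1:5)))),
               "at least 8")
})

test_that("single-exponential recovery at 1% noise, and recovery bias over replicates", {
  k <- 1e-3
  tt <- seq(0, 5 * log(2) / k, length.out = 200)
  set.seed(11)
  y <- 1 * exp(-k * tt) + rnorm(200, 0, 0.01)
  fit <- fit_single_exponential(time_course(tt, y))
  expect_equal(fit$k_app_1, k, tolerance = 0.02)

  # bias over 500 replicates stays below 0.5% of the true rate
  set.seed(12)
  ks <- replicate(500, {
    yy <- exp(-k * tt) + rnorm(200, 0, 0.01)
    fit_single_exponential(time_course(tt, yy))$k_app_1
  })
  expect_lt(abs(mean(ks) / k - 1), 0.005)
})

test_that("double-exponential component selection follows the amplitude-share rule", {
  tt <- seq(0, 5 * log(2) / 1e-4, by = 200)
  # dominant fast component: reported rate is the fast one
  y <- 0.1 + 0.7 * exp(-1e-2 * tt) + 0.3 * exp(-1e-4 * tt)
  fit <- fit_double_exponential(time_course(tt, y))
  expect_gte(fit$k_app_1, fit$k_app_2)
  expect_equal(fit$reported_rate, 1e-2, tolerance = 0.01)
  expect_match(fit$rate_selection, "faster component")
  # tiny fast amplitude: the larger-amplitude (slow) component is reported
  y2 <- 0.1 + 0.05 * exp(-1e-2 * tt) + 0.95 * exp(-1e-4 * tt)
  fit2 <- fit_double_exponential(time_course(tt, y2))
  expect_equal(fit2$reported_rate, 1e-4, tolerance = 0.01)
  expect_match(fit2$rate_selection, "larger-amplitude")
})

test_that("indistinguishable double-exponential components degrade to a single fit", {
  tt <- seq(0, 2e4, by = 100)
  y <- 0.5 * exp(-2e-4 * tt) + 0.5 * exp(-2.2e-4 * tt)
  expect_warning(fit <- fit_double_exponential(time_course(tt, y)),
                 "indistinguishable")
  expect_true(fit$degraded)
  expect_equal(fit$kind, "single")
  expect_equal(fit$reported_rate, 2.1e-4, tolerance = 0.05)
})

test_that("fits are invariant to affine rescaling of the signal axis", {
  k <- 5e-3
  tt <- seq(0, 1500, by = 10)
  set.seed(21)
  y <- 0.3 + exp(-k * tt) + rnorm(length(tt), 0, 0.004)
  f1 <- fit_single_exponential(time_course(tt, y))
  f2 <- fit_single_exponential(time_course(tt, 37 * y - 5))
  expect_equal(f2$k_app_1, f1$k_app_1, tolerance = 1e-9)
  expect_equal(f2$S1, 37 * f1$S1, tolerance = 1e-6)

  y2 <- 0.6 * exp(-1e-2 * tt) + 0.4 * exp(-5e-4 * tt)
  d1 <- fit_double_exponential(time_course(tt, y2))
  d2 <- fit_double_exponential(time_course(tt, 11 * y2 + 3))
  expect_equal(d2$k_app_1, d1$k_app_1, tolerance = 1e-6)
  expect_equal(d2$k_app_2, d1$k_app_2, tolerance = 1e-6)
})

test_that("multi-start seed grids agree on the best objective", {
  k <- 2e-3
  tt <- seq(0, 2500, by = 10)
  set.seed(31)
  y <- exp(-k * tt) + rnorm(length(tt), 0, 0.005)
  seeds <- 10^seq(-5, -1, length.out = 5)
  fits <- lapply(seq_along(seeds), function(i)
    fit_single_exponential(time_course(tt, y),
                           rate_seeds = seeds[c(i, i %% 5 + 1)]))
  rms <- vapply(fits, `[[`, numeric(1), "rms")
  expect_lt(diff(range(rms)) / min(rms), 1e-6)
})

test_that("dose-response laws recover exact parameters from exact points", {
  Eg <- 2e-6 / 2^(7:0)
  kv <- kapp_linear(Eg, 1e5, 1e-4)
  lin <- fit_dose_response(Eg, kv, "linear")
  expect_equal(lin$params[["k_on"]], 1e5, tolerance = 1e-8)
  expect_equal(lin$params[["k_off"]], 1e-4, tolerance = 1e-8)

  kh <- kapp_hyperbolic(Eg, 1e-2, 3e-7, 1e-5)
  hyp <- fit_dose_response(Eg, kh, "hyperbolic")
  expect_equal(hyp$params[["k_max"]], 1e-2, tolerance = 1e-6)
  expect_equal(hyp$params[["K_half"]], 3e-7, tolerance = 1e-6)
  expect_equal(hyp$params[["k_base"]], 1e-5, tolerance = 1e-4)

  # constrained variant: only K_half free
  con <- fit_dose_response(Eg, kh, "hyperbolic",
                           fix = list(k_max = 1e-2, k_base = 1e-5))
  expect_equal(con$params[["K_half"]], 3e-7, tolerance = 1e-6)

  # saturation warning when max conc is below K_half
  expect_warning(fit_dose_response(Eg, kapp_hyperbolic(Eg, 1e-2, 1e-4, 1e-5),
                                   "hyperbolic"),
                 "saturation not approached")
})

test_that("conformational-selection law recovers k_switch from eigenvalue-exact series", {
  Eg <- 4e-6 / 2^(11:0)
  kv <- kapp_conformational_selection(Eg, 2e-3, 5e-2, 1e5, 5e-5)
  fit <- fit_dose_response(Eg, kv, "conformational_selection")
  expect_equal(fit$params[["k_switch"]], 2e-3, tolerance = 0.05)
  expect_lte(fit$params[["k_off"]], 1e-4 * (1 + 1e-9))  # box bound, as observed
})

test_that("FP isotherm fit recovers K_d and flags tight binding", {
  sim <- gen_fp_titration(1e-8, 5e-10, P0 = 40, P1 = 160, top_conc = 1e-6,
                          noise = noise_model(sigma = 0, seed = 1))
  fit <- fit_isotherm(sim$host_conc_M, sim$polarization_mP, 5e-10)
  expect_equal(fit$K_d, 1e-8, tolerance = 0.01)
  expect_false(fit$tight_binding)

  tight <- gen_fp_titration(1e-11, 1e-9, top_conc = 1e-6,
                            noise = noise_model(sigma = 0, seed = 1))
  tf <- fit_isotherm(tight$host_conc_M, tight$polarization_mP, 1e-9)
  expect_true(tf$tight_binding)
  expect_match(tf$K_d_report, "K_d < 1e-09")

  flat <- rep(50, 24)
  expect_error(fit_isotherm(sim$host_conc_M, flat, 5e-10), "fit failure")
})

test_that("reverse facilitated dissociation recovers the hyperbolic law", {
  truth <- list(k_off_TH_E = 1e-2, K_half = 1e-6, k_off_HE = 1e-5,
                S0 = 30, S1 = 150, T_conc = c(0, 1e-6 / 2^(8:0)))
  courses <- gen_competition_courses("reverse", truth, dt = 5,
                                     noise = noise_model(sigma = 0, seed = 1))
  fit <- fit_reverse_fd(courses)
  expect_equal(fit$params[["k_off_TH_E"]], 1e-2, tolerance = 0.02)
  expect_equal(fit$params[["K_half"]], 1e-6, tolerance = 0.02)
  expect_equal(fit$params[["k_off_HE"]], 1e-5, tolerance = 0.02)
  # zero-target course decays at the base effector off-rate
  zero <- which(vapply(courses, `[[`, numeric(1), "conc") == 0)
  expect_equal(fit$course_fits[[zero]]$reported_rate, 1e-5, tolerance = 1e-4)
  # midpoint identity at [T] = K_half
  k_mid <- kapp_hyperbolic(truth$K_half, truth$k_off_TH_E, truth$K_half,
                           truth$k_off_HE)
  expect_equal(k_mid, truth$k_off_HE + truth$k_off_TH_E / 2,
               tolerance = 1e-12)
  # missing baseline course is rejected
  expect_error(fit_reverse_fd(courses[-zero]), "zero-target")
})

test_that("sigmoid drift is fitted on the reference and subtracted exactly", {
  drift <- list(S0 = 5, S1 = 20, k = 0.01, t_half = 800)
  sim <- gen_competition_courses("chain", list(k_app = 3e-3, S0 = 0, S1 = 100),
                                 t_max = 2000, dt = 2,
                                 noise = noise_model(sigma = 0, seed = 1),
                                 drift = drift)
  corrected <- subtract_sigmoid_drift(sim[[1]], sim[[2]])
  expect_lt(max(abs(corrected$signal - 100 * exp(-3e-3 * corrected$times))),
            1e-6)
  d <- attr(corrected, "drift")
  expect_equal(d$kind, "sigmoid")
  # midpoint identity of the fitted drift
  mid <- d$S0 + d$S1 / (1 + exp(-d$k * 0))
  expect_equal(mid, d$S0 + d$S1 / 2, tolerance = 1e-9)
  expect_equal(d$t_half, 800, tolerance = 0.01)

  # constant reference reduces to constant subtraction
  ref_const <- time_course(sim[[2]]$times, rep(7, length(sim[[2]]$times)))
  corr2 <- subtract_sigmoid_drift(sim[[1]], ref_const)
  expect_equal(corr2$signal, sim[[1]]$signal - 7, tolerance = 1e-6)
})
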