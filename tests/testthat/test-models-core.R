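# Domain types, reaction networks, ODE simulation and closed-form rate laws.

test_that("network topologies contain exactly the mechanism-defining reactions", {
  r <- full_rates()

  me <- build_network("mutually_exclusive", r)
  expect_false("THE" %in% me$species)

  cs <- build_network("conformational_selection", r)
  producers <- Filter(function(rx) "THE" %in% names(rx$products),
                      cs$reactions)
  via_Y <- vapply(producers, function(rx)
    all(sort(names(rx$reactants)) %in% sort(c("TH_Y", "E", "T", "HE"))),
    logical(1))
  # THE forms only from TH_Y + E or by target rebinding HE, never from TH_X
  expect_false(any(vapply(producers, function(rx)
    "TH_X" %in% names(rx$reactants), logical(1))))
  expect_true(any(vapply(producers, function(rx)
    setequal(names(rx$reactants), c("TH_Y", "E")), logical(1))))

  ifn <- build_network("induced_fit", r)
  expect_true(any(vapply(ifn$reactions, function(rx)
    setequal(names(rx$reactants), c("TH_X", "E")), logical(1))))
  expect_false("TH_Y" %in% ifn$species)
})

test_that("missing required rates raise a configuration error naming them", {
  r <- rate_constants(k_on_TH = 1e5, k_off_TH = 9e-5,
                      k_on_HE = 1e6, k_off_HE = 5e-6)
  expect_error(build_network("conformational_selection", r), "k_switch")
  expect_error(build_network("induced_fit", r), "k_on_THE_viaE")
  expect_silent(build_network("mutually_exclusive", r))
})

test_that("a single dissociation reaction integrates to the exact exponential", {
  r <- rate_constants(k_on_TH = 0, k_off_TH = 1e-3,
                      k_on_HE = 0, k_off_HE = 0)
  net <- build_network("mutually_exclusive", r)
  k <- 1e-3
  tt <- c(0, log(2) / k / 2, log(2) / k, 3 * log(2) / k)
  traj <- simulate_network(net, c(TH = 1e-6), tt, rtol = 1e-10, atol = 1e-16)
  expect_equal(traj[, "TH"] / 1e-6, exp(-k * tt), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(unname(traj[3, "TH"] / 1e-6), 0.5, tolerance = 1e-7)
})

test_that("trajectories of first-order linear networks match the matrix exponential", {
  skip_if_not_installed("Matrix")
  # with all on-rates zero the conformational-selection network is purely
  # first-order (switching + three dissociations); the matrix exponential
  # of the rate matrix assembled from the reaction list is an oracle
  # independent of the ODE integrator
  net <- build_network("conformational_selection",
                       rate_constants(k_on_TH = 0, k_off_TH = 9e-5,
                                      k_on_HE = 0, k_off_HE = 5e-6,
                                      k_on_THE_viaE = 0, k_off_THE_toE = 5e-5,
                                      k_on_THE_viaT = 0, k_off_THE_toT = 5e-2,
                                      k_switch = 2e-3, k_unswitch = 5e-2))
  sp <- net$species
  A <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (rx in net$reactions) {
    if (rx$k == 0) next
    from <- names(rx$reactants)
    stopifnot(length(from) == 1)   # all remaining reactions are first-order
    A[from, from] <- A[from, from] - rx$k
    for (to in names(rx$products)) A[to, from] <- A[to, from] + rx$k
  }
  y0 <- stats::setNames(numeric(length(sp)), sp)
  y0["TH_X"] <- 0.6; y0["THE"] <- 0.4
  tt <- c(0, 10, 100, 1000, 5000, 2e4)
  traj <- simulate_network(net, y0[y0 > 0], tt, rtol = 1e-10, atol = 1e-14)
  for (i in seq_along(tt)) {
    ref <- as.numeric(Matrix::expm(A * tt[i]) %*% y0)
    expect_lt(max(abs(traj[i, sp] - ref)), 1e-8)
  }
})

test_that("induced fit releases bound target no slower than conformational selection", {
  r <- full_rates()
  E <- 1e-5          # saturating effector
  C0 <- 1e-8         # target pre-bound as TH_X
  tt <- seq(0, 4000, by = 5)
  half_time <- function(topology) {
    net <- build_network(topology, r)
    traj <- simulate_network(net, c(TH_X = C0, E = E), tt)
    bound_cols <- intersect(c("TH_X", "TH_Y", "THE"), colnames(traj))
    frac <- rowSums(traj[, bound_cols, drop = FALSE]) / C0
    i <- which(frac <= 0.5)[1]
    tt[i - 1] + (tt[i] - tt[i - 1]) * (frac[i - 1] - 0.5) /
      (frac[i - 1] - frac[i])
  }
  expect_lte(half_time("induced_fit"), half_time("conformational_selection"))
})

test_that("mass conservation holds along trajectories of all topologies", {
  r <- full_rates()
  for (topo in c("mutually_exclusive", "conformational_selection",
                 "induced_fit")) {
    net <- build_network(topo, r)
    init <- c(T = 2e-7, H = 1e-7, E = 5e-7)
    traj <- simulate_network(net, init, seq(0, 5000, by = 100))
    tot <- conservation_totals(net, traj)
    drift <- abs(sweep(tot, 2, tot[1, ], "/") - 1)
    expect_lt(max(drift), 1e-6)
  }
})

test_that("cycle-consistent rates reach detailed-balance equilibrium", {
  r <- rate_constants_cyclic(
    k_on_TH = 1e5, k_off_TH = 9e-5, k_on_HE = 1e6, k_off_HE = 5e-6,
    k_on_THE_viaE = 1e5, k_off_THE_toE = 5e-3, k_on_THE_viaT = 1e4,
    solve_for = "k_off_THE_toT")
  # cycle product of equilibrium constants must close
  lhs <- (r$k_on_TH / r$k_off_TH) * (r$k_on_THE_viaE / r$k_off_THE_toE)
  rhs <- (r$k_on_HE / r$k_off_HE) * (r$k_on_THE_viaT / r$k_off_THE_toT)
  expect_equal(lhs / rhs, 1, tolerance = 1e-12)
  # allosteric-coupling identity follows from the closed cycle
  cr <- coupling_ratio(r)
  expect_equal(unname(cr["target"]), unname(cr["effector"]),
               tolerance = 1e-12)

  net <- build_network("induced_fit", r)
  init <- c(T = 1e-7, H = 1e-7, E = 1e-7)
  t_eq <- 5e6
  traj <- simulate_network(net, init, c(t_eq / 2, t_eq))
  eq <- traj[2, ]
  # equilibrium ratios against the independent equilibrium constants
  expect_equal(eq[["TH_X"]] / (eq[["T"]] * eq[["H"]]),
               r$k_on_TH / r$k_off_TH, tolerance = 1e-3)
  expect_equal(eq[["THE"]] / (eq[["TH_X"]] * eq[["E"]]),
               r$k_on_THE_viaE / r$k_off_THE_toE, tolerance = 1e-3)
  expect_equal(eq[["HE"]] / (eq[["H"]] * eq[["E"]]),
               r$k_on_HE / r$k_off_HE, tolerance = 1e-3)
})

test_that("linear apparent-rate law obeys arithmetic and linearity", {
  expect_identical(kapp_linear(0, 1e7, 3e-4), 3e-4)
  expect_equal(kapp_linear(1e-6, 1e5, 1e-4), 0.1001, tolerance = 1e-12)
  k1 <- kapp_linear(2e-7, 1e5, 1e-4) - 1e-4
  k2 <- kapp_linear(4e-7, 1e5, 1e-4) - 1e-4
  expect_equal(k2 / k1, 2, tolerance = 1e-12)
})

test_that("conformational-selection law: limits and eigenvalue equivalence", {
  ks <- 2e-3; ku <- 5e-2; kon <- 1e5; koff <- 5e-5
  # [E] = 0 collapses to min(k_switch + k_unswitch, k_off)
  expect_equal(kapp_conformational_selection(0, ks, ku, kon, koff),
               min(ks + ku, koff), tolerance = 1e-12)
  # saturation at k_switch
  E_big <- 1e6 * ks / kon
  expect_equal(kapp_conformational_selection(E_big, ks, ku, kon, koff),
               ks, tolerance = 1e-3)
  # equals the slow eigenvalue of the 3-state linear system, 100 random sets
  set.seed(101)
  for (i in 1:100) {
    p <- 10^stats::runif(4, c(-4, -3, 3, -6), c(-1, 0, 6, -3))
    E <- 10^stats::runif(1, -8, -4)
    kf <- kapp_conformational_selection(E, p[1], p[2], p[3], p[4])
    A <- rbind(c(-p[1], p[2], 0),
               c(p[1], -(p[2] + p[3] * E), p[4]),
               c(0, p[3] * E, -p[4]))
    ev <- sort(abs(eigen(A, only.values = TRUE)$values))
    slow <- ev[ev > max(ev) * 1e-12][1]
    expect_equal(kf, slow, tolerance = 1e-8)
  }
  # monotone non-decreasing in [E]
  Eg <- 10^seq(-9, -4, length.out = 40)
  kv <- kapp_conformational_selection(Eg, ks, ku, kon, koff)
  expect_true(all(diff(kv) >= -1e-15))
})

test_that("hyperbolic law: base, saturation and midpoint identities", {
  expect_identical(kapp_hyperbolic(0, 1e-2, 1e-6, 1e-5), 1e-5)
  expect_equal(kapp_hyperbolic(1e6, 1e-2, 1e-6, 1e-5), 1e-2 + 1e-5,
               tolerance = 1e-6)
  expect_equal(kapp_hyperbolic(1e-6, 1e-2, 1e-6, 1e-5), 1e-5 + 5e-3,
               tolerance = 1e-12)
  # agrees with the linear law in the K_half -> Inf limit with
  # k_max / K_half fixed
  kon <- 1e5; Kh <- 1e3
  Eg <- 10^seq(-9, -5, length.out = 30)
  expect_equal(kapp_hyperbolic(Eg, kon * Kh, Kh, 1e-4),
               kapp_linear(Eg, kon, 1e-4), tolerance = 1e-6)
})

test_that("quadratic fraction bound: limits and closed-form value", {
  expect_identical(fraction_bound(0, 1e-9, 1e-9), 0)
  # dilute-probe limit
  expect_equal(fraction_bound(1e-8, 0, 1e-8), 0.5, tolerance = 1e-12)
  expect_equal(fraction_bound(3e-8, 1e-15, 1e-8), 0.75, tolerance = 1e-6)
  # H = E = K_d gives (3 - sqrt(5)) / 2
  expect_equal(fraction_bound(1e-9, 1e-9, 1e-9), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  # monotone increasing in H, bounded in [0, 1]
  fb <- fraction_bound(10^seq(-12, -5, length.out = 50), 1e-9, 1e-8)
  expect_true(all(diff(fb) > 0))
  expect_true(all(fb >= 0 & fb <= 1))
})

test_that("polarization formula and degenerate input", {
  expect_identical(polarization(5, 5), 0)
  expect_identical(polarization(7, 0), 1000)
  expect_identical(polarization(3, 1), 500)
  expect_error(polarization(0, 0), "undefined")
})

test_that("rate constants serialize to JSON and back with units", {
  r <- full_rates()
  path <- tempfile(fileext = ".json")
  write_rates_json(r, path, topology = "induced_fit")
  back <- read_rates_json(path)
  expect_identical(back$topology, "induced_fit")
  expect_equal(unclass(back$rates), unclass(r), tolerance = 1e-15)
  expect_error(rate_constants(k_on_TH = -1), "non-negative")
})
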