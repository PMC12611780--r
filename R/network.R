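#' Build a mass-action reaction network for a competition mechanism
#'
#' Assembles the species list and elementary reactions for one of the three
#' competition topologies between target (T), host (H) and effector (E):
#'
#' * `mutually_exclusive`: no ternary species; E binds only free H.
#' * `conformational_selection`: the target:host complex interconverts
#'   between a closed state `TH_X` and an open state `TH_Y`
#'   (`k_switch`/`k_unswitch`); the effector binds only `TH_Y`.
#' * `induced_fit`: the (flexible) effector engages the closed complex
#'   `TH_X` directly and commits to the strained ternary complex in a single
#'   collapsed step carrying `k_on_THE_viaE`.
#'
#' In the two facilitated-dissociation topologies the ternary complex can
#' release the target (`k_off_THE_toT`) and re-form from T + HE
#' (`k_on_THE_viaT`), and free host binds effector (`k_on_HE`/`k_off_HE`).
#'
#' @param topology one of `"mutually_exclusive"`,
#'   `"conformational_selection"`, `"induced_fit"`.
#' @param rates a [rate_constants()] object; rates the topology never uses
#'   may be `NA`.
#' @return An object of class `reaction_network` with elements `topology`,
#'   `species`, `reactions` (list of reactant/product multisets plus rate),
#'   the stoichiometry matrix `S` and reactant-order matrix `order_mat`.
#' @export
build_network <- function(topology = c("mutually_exclusive",
                                       "conformational_selection",
                                       "induced_fit"),
                          rates) {
  topology <- match.arg(topology)
  stopifnot(inherits(rates, "rate_constants"))

  rxn <- function(reactants, products, rate_name)
    list(reactants = reactants, products = products, rate_name = rate_name)

  reactions <- switch(topology,
    mutually_exclusive = list(
      rxn(c(T = 1, H = 1), c(TH = 1),       "k_on_TH"),
      rxn(c(TH = 1),       c(T = 1, H = 1), "k_off_TH"),
      rxn(c(H = 1, E = 1), c(HE = 1),       "k_on_HE"),
      rxn(c(HE = 1),       c(H = 1, E = 1), "k_off_HE")
    ),
    conformational_selection = list(
      rxn(c(T = 1, H = 1),    c(TH_X = 1),         "k_on_TH"),
      rxn(c(TH_X = 1),        c(T = 1, H = 1),     "k_off_TH"),
      rxn(c(TH_X = 1),        c(TH_Y = 1),         "k_switch"),
      rxn(c(TH_Y = 1),        c(TH_X = 1),         "k_unswitch"),
      rxn(c(TH_Y = 1, E = 1), c(THE = 1),          "k_on_THE_viaE"),
      rxn(c(THE = 1),         c(TH_Y = 1, E = 1),  "k_off_THE_toE"),
      rxn(c(THE = 1),         c(T = 1, HE = 1),    "k_off_THE_toT"),
      rxn(c(T = 1, HE = 1),   c(THE = 1),          "k_on_THE_viaT"),
      rxn(c(H = 1, E = 1),    c(HE = 1),           "k_on_HE"),
      rxn(c(HE = 1),          c(H = 1, E = 1),     "k_off_HE")
    ),
    induced_fit = list(
      rxn(c(T = 1, H = 1),    c(TH_X = 1),         "k_on_TH"),
      rxn(c(TH_X = 1),        c(T = 1, H = 1),     "k_off_TH"),
      rxn(c(TH_X = 1, E = 1), c(THE = 1),          "k_on_THE_viaE"),
      rxn(c(THE = 1),         c(TH_X = 1, E = 1),  "k_off_THE_toE"),
      rxn(c(THE = 1),         c(T = 1, HE = 1),    "k_off_THE_toT"),
      rxn(c(T = 1, HE = 1),   c(THE = 1),          "k_on_THE_viaT"),
      rxn(c(H = 1, E = 1),    c(HE = 1),           "k_on_HE"),
      rxn(c(HE = 1),          c(H = 1, E = 1),     "k_off_HE")
    )
  )

  k <- vapply(reactions, function(rx) {
    v <- rates[[rx$rate_name]]
    if (is.na(v))
      stop("rate '", rx$rate_name, "' is required for topology '", topology,
           "' but is missing (NA)", call. = FALSE)
    v
  }, numeric(1))
  for (i in seq_along(reactions)) reactions[[i]]$k <- k[i]

  species <- unique(unlist(lapply(reactions, function(rx)
    c(names(rx$reactants), names(rx$products)))))

  nr <- length(reactions)
  ns <- length(species)
  S <- matrix(0, ns, nr, dimnames = list(species, NULL))
  order_mat <- matrix(0, ns, nr, dimnames = list(species, NULL))
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    S[names(rx$reactants), j] <- S[names(rx$reactants), j] - rx$reactants
    S[names(rx$products), j]  <- S[names(rx$products), j] + rx$products
    order_mat[names(rx$reactants), j] <- rx$reactants
  }

  structure(list(topology = topology, species = species,
                 reactions = reactions, S = S, order_mat = order_mat,
                 k = k),
            class = "reaction_network")
}

# elemental composition of every species the topologies can produce,
# used for conservation checks
.species_composition <- function(species) {
  comp <- rbind(
    T    = c(T = 1, H = 0, E = 0),
    H    = c(T = 0, H = 1, E = 0),
    E    = c(T = 0, H = 0, E = 1),
    TH   = c(T = 1, H = 1, E = 0),
    TH_X = c(T = 1, H = 1, E = 0),
    TH_Y = c(T = 1, H = 1, E = 0),
    HE   = c(T = 0, H = 1, E = 1),
    THE  = c(T = 1, H = 1, E = 1)
  )
  unknown <- setdiff(species, rownames(comp))
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  comp[species, , drop = FALSE]
}

#' Mass-action right-hand side of a reaction network
#'
#' Returns a function `(t, y, parms)` in the form expected by
#' [deSolve::ode()], computing pure mass-action fluxes from the network's
#' stoichiometry.
#'
#' @param network a [build_network()] object.
#' @return A derivative function for deSolve.
#' @export
network_rhs <- function(network) {
  S <- network$S
  om <- network$order_mat
  k <- network$k
  nr <- length(k)
  function(t, y, parms) {
    rates <- k
    for (j in seq_len(nr)) {
      idx <- which(om[, j] > 0)
      for (i in idx) rates[j] <- rates[j] * y[i]^om[i, j]
    }
    list(as.vector(S %*% rates))
  }
}

#' Integrate a reaction network
#'
#' Deterministic integration of the mass-action ODE system with a
#' stiff-capable method. Tolerances default to rtol 1e-8 / atol 1e-12
#' because the rates span many orders of magnitude and conservation
#' invariants are checked tightly downstream. Negative concentrations
#' beyond tolerance are treated as integrator failure, not clipped.
#'
#' @param network a [build_network()] object.
#' @param initial named numeric vector of initial concentrations (M);
#'   species not named start at zero.
#' @param times strictly increasing vector of times (s).
#' @param rtol,atol relative/absolute integrator tolerances.
#' @param method deSolve method, default `"lsoda"`.
#' @return Matrix with a `time` column and one column per species.
#' @export
simulate_network <- function(network, initial, times,
                             rtol = 1e-8, atol = 1e-12, method = "lsoda") {
  stopifnot(inherits(network, "reaction_network"))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  y0 <- stats::setNames(numeric(length(network$species)), network$species)
  if (length(initial)) {
    unknown <- setdiff(names(initial), network$species)
    if (length(unknown))
      stop("initial names species absent from the network: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(initial < 0))
      stop("initial concentrations must be non-negative", call. = FALSE)
    y0[names(initial)] <- initial
  }
  out <- deSolve::ode(y = y0, times = times, func = network_rhs(network),
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("integrator failure at t = ", max(out[, "time"]), call. = FALSE)
  if (nrow(out) < length(times))
    stop("integrator failure: last accepted time ", max(out[, "time"]),
         call. = FALSE)
  conc <- out[, network$species, drop = FALSE]
  neg_tol <- atol * 1e3 + rtol * max(abs(conc))
  if (min(conc) < -neg_tol)
    stop("integrator produced negative concentrations beyond tolerance (min ",
         format(min(conc)), ") at t <= ", max(out[, "time"]), call. = FALSE)
  class(out) <- c("matrix", "array")
  out
}

#' Conserved totals of target, host and effector along a trajectory
#'
#' @param network a [build_network()] object.
#' @param traj a trajectory from [simulate_network()].
#' @return Matrix with columns `T`, `H`, `E`: total concentration of each
#'   conserved unit at every time point.
#' @export
conservation_totals <- function(network, traj) {
  comp <- .species_composition(network$species)
  traj[, network$species, drop = FALSE] %*% comp
}
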