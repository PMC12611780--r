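#' Microscopic rate constants of a target/host/effector network
#'
#' Bundles all rate constants of the competition network between a target
#' (T), a switchable host binder (H, with conformational states X and Y) and
#' an effector (E). On-rates are in M^-1 s^-1, off-rates and conformational
#' rates in s^-1; all concentrations used with these rates must be molar.
#' Rates that a given mechanism topology never uses may be left `NA`.
#'
#' @param k_on_TH association rate of target + host -> TH (M^-1 s^-1)
#' @param k_off_TH dissociation rate of the target:host complex (s^-1)
#' @param k_on_HE association rate of host + effector -> HE (M^-1 s^-1)
#' @param k_off_HE dissociation rate of the host:effector complex (s^-1)
#' @param k_on_THE_viaE effector association to the target:host complex
#'   (M^-1 s^-1)
#' @param k_off_THE_toE effector dissociation from the ternary complex (s^-1)
#' @param k_on_THE_viaT target association to the host:effector complex
#'   (M^-1 s^-1)
#' @param k_off_THE_toT target dissociation from the ternary complex (s^-1)
#' @param k_switch TH_X -> TH_Y conformational rate (s^-1)
#' @param k_unswitch TH_Y -> TH_X conformational rate (s^-1)
#' @param k_off_THn target dissociation from effector-unresponsive host (s^-1)
#' @return An object of class `rate_constants` (a named list).
#' @seealso [rate_constants_cyclic()] for a thermodynamically consistent
#'   constructor, [coupling_ratio()] for the allosteric-coupling identity.
#' @export
rate_constants <- function(k_on_TH = NA_real_, k_off_TH = NA_real_,
                           k_on_HE = NA_real_, k_off_HE = NA_real_,
                           k_on_THE_viaE = NA_real_, k_off_THE_toE = NA_real_,
                           k_on_THE_viaT = NA_real_, k_off_THE_toT = NA_real_,
                           k_switch = NA_real_, k_unswitch = NA_real_,
                           k_off_THn = NA_real_) {
  r <- list(
    k_on_TH = k_on_TH, k_off_TH = k_off_TH,
    k_on_HE = k_on_HE, k_off_HE = k_off_HE,
    k_on_THE_viaE = k_on_THE_viaE, k_off_THE_toE = k_off_THE_toE,
    k_on_THE_viaT = k_on_THE_viaT, k_off_THE_toT = k_off_THE_toT,
    k_switch = k_switch, k_unswitch = k_unswitch,
    k_off_THn = k_off_THn
  )
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L)
      stop("rate '", nm, "' must be a single numeric value", call. = FALSE)
    if (!is.na(v) && (!is.finite(v) || v < 0))
      stop("rate '", nm, "' must be finite and non-negative, got ", v,
           call. = FALSE)
    r[[nm]] <- as.numeric(v)
  }
  structure(r, class = "rate_constants")
}

# rate names carrying M^-1 s^-1 units; everything else is s^-1
.on_rate_names <- c("k_on_TH", "k_on_HE", "k_on_THE_viaE", "k_on_THE_viaT")

#' Rate constants with an enforced closed thermodynamic cycle
#'
#' The binding cycle T + H + E <-> TH <-> THE <-> HE + T requires the product
#' of equilibrium constants around the cycle to equal one:
#' `(k_on_TH/k_off_TH) * (k_on_THE_viaE/k_off_THE_toE) ==
#'  (k_on_HE/k_off_HE) * (k_on_THE_viaT/k_off_THE_toT)`.
#' This constructor leaves one rate free (passed as `NA`) and solves for it
#' so the constraint holds exactly.
#'
#' @inheritParams rate_constants
#' @param solve_for name of the rate to solve for; it must be `NA` among the
#'   supplied arguments and must be one of the eight cycle rates.
#' @param ... remaining rates, passed to [rate_constants()].
#' @return A `rate_constants` object satisfying the cycle constraint.
#' @export
rate_constants_cyclic <- function(..., solve_for = "k_off_THE_toT") {
  cyc <- c("k_on_TH", "k_off_TH", "k_on_HE", "k_off_HE",
           "k_on_THE_viaE", "k_off_THE_toE", "k_on_THE_viaT", "k_off_THE_toT")
  if (!solve_for %in% cyc)
    stop("solve_for must be one of the cycle rates: ",
         paste(cyc, collapse = ", "), call. = FALSE)
  args <- list(...)
  args[[solve_for]] <- NULL
  r <- do.call(rate_constants, args)
  need <- setdiff(cyc, solve_for)
  miss <- need[vapply(need, function(nm) is.na(r[[nm]]), logical(1))]
  if (length(miss))
    stop("cycle closure needs rates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  # lhs path: T+H -> TH -> THE ; rhs path: H+E -> HE -> THE
  lhs <- (r$k_on_TH / r$k_off_TH) * (r$k_on_THE_viaE / r$k_off_THE_toE)
  rhs <- (r$k_on_HE / r$k_off_HE) * (r$k_on_THE_viaT / r$k_off_THE_toT)
  val <- switch(solve_for,
    k_on_THE_viaT = lhs / (r$k_on_HE / r$k_off_HE) * r$k_off_THE_toT,
    k_off_THE_toT = (r$k_on_HE / r$k_off_HE) * r$k_on_THE_viaT / lhs,
    k_on_HE = lhs / (r$k_on_THE_viaT / r$k_off_THE_toT) * r$k_off_HE,
    k_off_HE = r$k_on_HE * (r$k_on_THE_viaT / r$k_off_THE_toT) / lhs,
    k_on_THE_viaE = rhs / (r$k_on_TH / r$k_off_TH) * r$k_off_THE_toE,
    k_off_THE_toE = (r$k_on_TH / r$k_off_TH) * r$k_on_THE_viaE / rhs,
    k_on_TH = rhs / (r$k_on_THE_viaE / r$k_off_THE_toE) * r$k_off_TH,
    k_off_TH = r$k_on_TH * (r$k_on_THE_viaE / r$k_off_THE_toE) / rhs
  )
  if (!is.finite(val) || val < 0)
    stop("cycle closure gives a non-finite or negative rate for ", solve_for,
         call. = FALSE)
  r[[solve_for]] <- val
  r
}

#' Allosteric-coupling ratio of a rate-constant set
#'
#' For a cycle-consistent set, the factor by which saturating effector
#' weakens target binding equals the factor by which saturating target
#' weakens effector binding. Returns both ratios so the identity can be
#' checked: `target = K_d(T, sat. E) / K_d(T)` and
#' `effector = K_d(E, sat. T) / K_d(E)`.
#'
#' @param rates a [rate_constants()] object with all eight cycle rates set.
#' @return Named numeric vector with elements `target` and `effector`.
#' @export
coupling_ratio <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  kd_T    <- rates$k_off_TH / rates$k_on_TH
  kd_T_E  <- rates$k_off_THE_toT / rates$k_on_THE_viaT
  kd_E    <- rates$k_off_HE / rates$k_on_HE
  kd_E_T  <- rates$k_off_THE_toE / rates$k_on_THE_viaE
  c(target = kd_T_E / kd_T, effector = kd_E_T / kd_E)
}

#' Write/read rate constants (and optional topology) as JSON
#'
#' Serialized with explicit unit strings and a schema version so runs are
#' self-describing.
#'
#' @param rates a [rate_constants()] object.
#' @param path file path.
#' @param topology optional mechanism topology string stored alongside.
#' @return `write_rates_json` returns `path` invisibly; `read_rates_json`
#'   returns a list with elements `rates` and `topology`.
#' @export
write_rates_json <- function(rates, path, topology = NULL) {
  stopifnot(inherits(rates, "rate_constants"))
  units <- ifelse(names(unclass(rates)) %in% .on_rate_names,
                  "M^-1 s^-1", "s^-1")
  names(units) <- names(unclass(rates))
  obj <- list(
    schema = "fdkin/rate_constants",
    schema_version = 1L,
    topology = topology,
    rates = unclass(rates),
    units = as.list(units)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_rates_json
#' @export
read_rates_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "fdkin/rate_constants"))
    stop("not a fdkin rate-constants file: ", path, call. = FALSE)
  rr <- obj$rates
  rr[vapply(rr, is.null, logical(1))] <- NA_real_
  rates <- do.call(rate_constants, lapply(rr, function(x)
    if (is.null(x)) NA_real_ else as.numeric(x)))
  list(rates = rates, topology = obj$topology)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (on-rates M^-1 s^-1, others s^-1):\n")
  v <- unlist(unclass(x))
  v <- v[!is.na(v)]
  for (nm in names(v)) cat(sprintf("  %-15s %g\n", nm, v[[nm]]))
  invisible(x)
}
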