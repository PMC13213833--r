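# gas constant in kcal/mol/K, used by every barrier <-> rate conversion
R_KCAL <- physical_constants$R / physical_constants$cal_to_J / 1000

# concentration standard-state factor (L/mol) for one unit of molecularity
standard_state_volume <- function(standard_state, T) {
  switch(standard_state,
         # gas-phase dG computed at P0 maps to concentration units via RT/P0
         gas_1atm = physical_constants$R * T / 101325 * 1000,
         gas_1bar = physical_constants$R * T / 1e5 * 1000,
         solution_1M = 1,
         rxnkin_stop("rxnkin_domain_error", "unknown standard state ",
                     dQuote(standard_state)))
}

#' Eyring rate constant from an activation free energy
#'
#' `k = kappa * (kB*T/h) * exp(-dG_act/(R*T))`. For molecularity `m > 1` the
#' pressure-based gas-phase free energy is converted to concentration units
#' by `(RT/P0)^(m-1)` (standard state `gas_1atm` or `gas_1bar`) or
#' `(1/C0)^(m-1)` with `C0 = 1 M` (`solution_1M`), giving
#' `M^-(m-1) s^-1`.
#'
#' @param dg_act activation free energy in kcal/mol.
#' @param T temperature in K.
#' @param kappa transmission coefficient (> 0, default 1: no tunneling).
#' @param molecularity integer >= 1.
#' @param standard_state `"gas_1atm"`, `"gas_1bar"` or `"solution_1M"`.
#' @return a list of class `rxnkin_rate` with `value` (s^-1 or
#'   M^-(m-1) s^-1), `molecularity` and `T`.
#' @export
eyring_rate <- function(dg_act, T, kappa = 1, molecularity = 1L,
                        standard_state = "solution_1M") {
  if (T <= 0 || kappa <= 0) {
    rxnkin_stop("rxnkin_domain_error", "eyring_rate requires T > 0, kappa > 0")
  }
  if (molecularity < 1) {
    rxnkin_stop("rxnkin_domain_error", "molecularity must be >= 1")
  }
  pc <- physical_constants
  k <- kappa * pc$kB * T / pc$h * exp(-dg_act / (R_KCAL * T))
  k <- k * standard_state_volume(standard_state, T)^(molecularity - 1)
  structure(list(value = k, molecularity = as.integer(molecularity), T = T),
            class = "rxnkin_rate")
}

#' @export
print.rxnkin_rate <- function(x, ...) {
  units <- if (x$molecularity == 1) "s^-1" else
    sprintf("M^-%d s^-1", x$molecularity - 1)
  cat(sprintf("<rate constant> k = %.6g %s at %.2f K\n", x$value, units, x$T))
  invisible(x)
}

#' Activation free energy from a rate constant
#'
#' Exact inverse of [eyring_rate()]:
#' `dG_act = -R*T*ln(k*h/(kappa*kB*T))` after undoing any standard-state
#' conversion for molecularity > 1.
#'
#' @param k rate constant (bare number or [eyring_rate()] result).
#' @param T temperature in K.
#' @param kappa transmission coefficient.
#' @param molecularity integer >= 1.
#' @param standard_state as in [eyring_rate()].
#' @return activation free energy in kcal/mol.
#' @export
gibbs_from_rate <- function(k, T, kappa = 1, molecularity = 1L,
                            standard_state = "solution_1M") {
  if (inherits(k, "rxnkin_rate")) {
    molecularity <- k$molecularity
    T <- k$T
    k <- k$value
  }
  if (k <= 0) rxnkin_stop("rxnkin_domain_error", "rate constant must be > 0")
  if (T <= 0 || kappa <= 0) {
    rxnkin_stop("rxnkin_domain_error", "require T > 0, kappa > 0")
  }
  pc <- physical_constants
  k0 <- k / standard_state_volume(standard_state, T)^(molecularity - 1)
  -R_KCAL * T * log(k0 * pc$h / (kappa * pc$kB * T))
}

#' Equilibrium constant from a reaction free energy
#'
#' `K = exp(-dG_rxn/(R*T))`; equals `k_f/k_r` of the corresponding
#' elementary step (detailed balance).
#'
#' @param dg_rxn reaction free energy in kcal/mol.
#' @param T temperature in K.
#' @return unitless equilibrium constant.
#' @export
equilibrium_constant <- function(dg_rxn, T) {
  if (T <= 0) rxnkin_stop("rxnkin_domain_error", "T must be > 0")
  exp(-dg_rxn / (R_KCAL * T))
}

#' Construct an elementary step
#'
#' A reversible step with named stoichiometries, an optional transition
#' state, and forward/reverse activation free energies. The invariant
#' `dg_forward - dg_reverse == dG_rxn` is enforced when both barriers are
#' given.
#'
#' @param reactants named numeric vector of stoichiometric counts.
#' @param products named numeric vector of stoichiometric counts.
#' @param dg_forward,dg_reverse activation free energies in kcal/mol.
#' @param ts transition-state name or NULL.
#' @param kappa transmission coefficient.
#' @param T temperature in K.
#' @return a list of class `rxnkin_step`.
#' @export
elementary_step <- function(reactants, products, dg_forward, dg_reverse,
                            ts = NULL, kappa = 1, T = 298.15) {
  stopifnot(!is.null(names(reactants)), !is.null(names(products)))
  structure(list(reactants = reactants, products = products,
                 ts = ts, dg_forward = dg_forward, dg_reverse = dg_reverse,
                 kappa = kappa, T = T),
            class = "rxnkin_step")
}

#' Forward and reverse rate constants of an elementary step
#'
#' From species Gibbs energies at temperature T:
#' `dG_act_f = G(TS) - sum G(reactants)`,
#' `dG_act_r = G(TS) - sum G(products)`, each fed to [eyring_rate()] with
#' the molecularity of its own side. Negative barriers (TS below the
#' connecting state, which plain RRHO can produce) trigger a warning but
#' are computed as-is.
#'
#' @param ts transition-state [species_record()] with thermochemistry.
#' @param reactants list of reactant [species_record()]s (repeat a species
#'   for stoichiometry > 1).
#' @param products list of product [species_record()]s.
#' @param T temperature in K; must match the species' thermochemistry.
#' @param kappa transmission coefficient.
#' @param standard_state as in [eyring_rate()].
#' @return list with `k_f`, `k_r` ([eyring_rate()] objects), `dg_forward`,
#'   `dg_reverse`, `dg_rxn` (kcal/mol).
#' @export
step_rates <- function(ts, reactants, products, T = NULL, kappa = 1,
                       standard_state = "solution_1M") {
  all_sp <- c(list(ts), reactants, products)
  missing_thermo <- vapply(all_sp, function(s) is.null(s$thermo), TRUE)
  if (any(missing_thermo)) {
    rxnkin_stop("rxnkin_state_error", "missing thermochemistry for: ",
                paste(vapply(all_sp[missing_thermo], `[[`, "", "name"),
                      collapse = ", "))
  }
  Ts <- vapply(all_sp, function(s) s$thermo$T, 0)
  if (is.null(T)) T <- Ts[1]
  if (max(abs(Ts - T)) > 1e-9) {
    rxnkin_stop("rxnkin_state_error",
                "species thermochemistry not all at T = ", T, " K")
  }
  ts_comp <- ts$composition
  r_comp <- sum_compositions(lapply(reactants, `[[`, "composition"))
  p_comp <- sum_compositions(lapply(products, `[[`, "composition"))
  if (!same_composition(ts_comp, r_comp) || !same_composition(ts_comp, p_comp)) {
    rxnkin_stop("rxnkin_composition_error",
                "step is not composition-balanced across reactants/TS/products")
  }
  g <- function(sp) sp$thermo$gibbs
  dgf <- g(ts) - sum(vapply(reactants, g, 0))
  dgr <- g(ts) - sum(vapply(products, g, 0))
  if (dgf < 0 || dgr < 0) {
    warning("negative activation free energy (TS below connecting state); ",
            "computing the Eyring rate anyway", call. = FALSE)
  }
  list(k_f = eyring_rate(dgf, T, kappa, length(reactants), standard_state),
       k_r = eyring_rate(dgr, T, kappa, length(products), standard_state),
       dg_forward = dgf, dg_reverse = dgr, dg_rxn = dgf - dgr)
}
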