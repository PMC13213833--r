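# run expr with a private RNG stream (seeded), restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic species record
#'
#' Produces a self-consistent random species: a plausible (but not
#' optimized) geometry built by perturbing atoms around the origin, an
#' electronic energy, harmonic frequencies (3N-6 modes, with exactly one
#' imaginary mode for the transition-state template) and a multiplicity.
#' Identical seeds give byte-identical records. Numeric fields are rounded
#' to the precision the ORCA-like emitter prints, so the
#' parse/emit round trip is exact.
#'
#' @param seed integer seed.
#' @param role `"minimum"`, `"transition_state"` or `"reference"`.
#' @param n_atoms number of atoms (default: random 2-8).
#' @param elements element pool to draw from.
#' @param energy_range electronic-energy range in Hartree.
#' @param freq_range real-mode wavenumber range in cm^-1.
#' @param name species name.
#' @return a [species_record()] (with geometry and frequencies set).
#' @export
make_species <- function(seed = 1L, role = "minimum", n_atoms = NULL,
                         elements = c("H", "C", "N", "O", "F", "Cl", "Br"),
                         energy_range = c(-250, -50),
                         freq_range = c(60, 3400),
                         name = paste0("SP", seed)) {
  with_seed(seed, {
    if (is.null(n_atoms)) n_atoms <- sample(2:8, 1)
    els <- sample(elements, n_atoms, replace = TRUE)
    # jittered cubic-lattice placement: plausible bond-scale spacing,
    # never coincident atoms
    grid <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * 1.5
    coords <- grid[seq_len(n_atoms), , drop = FALSE] +
      matrix(stats::runif(3 * n_atoms, -0.3, 0.3), ncol = 3)
    coords <- round(coords, 6)
    geom <- geometry(els, coords, comment = name)
    n_modes <- max(3 * n_atoms - 6, 1)
    freqs <- round(sort(stats::runif(n_modes, freq_range[1], freq_range[2])),
                   2)
    if (role == "transition_state") {
      freqs[1] <- -round(stats::runif(1, 200, 1800), 2)
    }
    energy <- round(stats::runif(1, energy_range[1], energy_range[2]), 9)
    mult <- sample(c(1L, 1L, 1L, 2L, 3L), 1)
    species_record(name, energy, role = role, geometry = geom,
                   frequencies = freqs, multiplicity = mult)
  })
}

#' Emit an ORCA-like frequency-output text for a record
#'
#' The exact grammar [parse_orca_like()] supports: a multiplicity line, a
#' `CARTESIAN COORDINATES (ANGSTROEM)` block (coordinates at 10 decimals),
#' a `FINAL SINGLE POINT ENERGY` line (9 decimals) and a
#' `VIBRATIONAL FREQUENCIES` block (2 decimals) whose first six entries are
#' the exact-zero translational/rotational placeholders. Parsing the emitted
#' text reproduces the record exactly.
#'
#' @param record a [species_record()] or [qc_record()].
#' @param n_zero_modes number of leading zero placeholder modes.
#' @return character vector of lines.
#' @export
make_orca_like_text <- function(record, n_zero_modes = 6L) {
  geom <- record$geometry
  freqs <- record$frequencies
  lines <- c(
    "                        * rxnkin synthetic quantum-chemistry output *",
    "",
    sprintf("Multiplicity           Mult            ....    %d",
            record$multiplicity),
    "")
  if (!is.null(geom)) {
    lines <- c(lines,
               "---------------------------------",
               "CARTESIAN COORDINATES (ANGSTROEM)",
               "---------------------------------",
               sprintf("  %-3s %15.10f %15.10f %15.10f", geom$elements,
                       geom$coordinates[, 1], geom$coordinates[, 2],
                       geom$coordinates[, 3]),
               "")
  }
  lines <- c(lines,
             sprintf("FINAL SINGLE POINT ENERGY %20.9f",
                     record$electronic_energy),
             "",
             "-----------------------",
             "VIBRATIONAL FREQUENCIES",
             "-----------------------",
             "")
  all_modes <- c(rep(0, n_zero_modes), freqs)
  lines <- c(lines,
             sprintf("%4d: %12.2f cm**-1", seq_along(all_modes) - 1L,
                     all_modes),
             "")
  lines
}

#' First-order decay network with its closed-form solution
#'
#' The textbook `A -> B` system: `c_A(t) = c0 * exp(-k t)`.
#'
#' @param k rate constant in s^-1 (>= 0).
#' @param c0 initial concentration of A in mol/L.
#' @param t_end integration window; default covers ~30 half-lives.
#' @return list with `problem` (an [mkm_problem()]) and `closed_form`
#'   (function of t returning c_A).
#' @export
make_first_order_network <- function(k, c0 = 1, t_end = NULL) {
  if (k < 0) rxnkin_stop("rxnkin_domain_error", "k must be >= 0")
  net <- build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                                 k_f = k, k_r = 0)))
  if (is.null(t_end)) t_end <- if (k > 0) 30 / k else 1
  list(problem = mkm_problem(net, c(A = c0), t_end = t_end),
       closed_form = function(t) c0 * exp(-k * t))
}

#' Two competing irreversible channels with analytic selectivity
#'
#' `A -> B` over a barrier `g_act_base` and `A -> C` over
#' `g_act_base + ddg`, both through [eyring_rate()] at temperature `T`. The
#' analytic selectivity toward B is
#' `S = k1/(k1+k2) = 1/(1 + exp(-ddg/(R*T)))`, independent of evaluation
#' time.
#'
#' @param ddg free-energy preference for the B channel in kcal/mol.
#' @param g_act_base barrier of the favored channel in kcal/mol.
#' @param T temperature in K.
#' @param c0 initial concentration of A.
#' @return list with `problem`, `selectivity_analytic`, `k1`, `k2`.
#' @export
make_competing_network <- function(ddg, g_act_base = 18, T = 373.15,
                                   c0 = 1) {
  if (T <= 0) rxnkin_stop("rxnkin_domain_error", "T must be > 0")
  k1 <- eyring_rate(g_act_base, T)$value
  k2 <- eyring_rate(g_act_base + ddg, T)$value
  net <- build_network(list(
    list(reactants = c(A = 1), products = c(B = 1), k_f = k1, k_r = 0),
    list(reactants = c(A = 1), products = c(C = 1), k_f = k2, k_r = 0)))
  t_end <- 40 / (k1 + k2)
  list(problem = mkm_problem(net, c(A = c0), t_end = t_end, T = T),
       selectivity_analytic = 1 / (1 + exp(-ddg / (R_KCAL * T))),
       k1 = k1, k2 = k2)
}

#' Synthetic Arrhenius rate table
#'
#' `k(T) = exp(lnA - Ea/(R*T))`, optionally with multiplicative log-normal
#' noise, for exercising the apparent-activation-energy fit.
#'
#' @param ea activation energy in kcal/mol.
#' @param lnA log pre-exponential factor.
#' @param temperatures temperatures in K (>= 2).
#' @param noise_sd standard deviation of the log-normal noise (0 = exact).
#' @param seed RNG seed for the noise.
#' @return data.frame with columns `T` and `rate`.
#' @export
make_arrhenius_dataset <- function(ea, lnA, temperatures, noise_sd = 0,
                                   seed = 1L) {
  if (length(temperatures) < 2) {
    rxnkin_stop("rxnkin_domain_error", "need at least 2 temperatures")
  }
  rates <- exp(lnA - ea / (R_KCAL * temperatures))
  if (noise_sd > 0) {
    rates <- with_seed(seed,
                       rates * exp(stats::rnorm(length(rates), 0, noise_sd)))
  }
  data.frame(T = temperatures, rate = rates)
}
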