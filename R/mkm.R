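#' Build a kinetic network from elementary steps
#'
#' Assembles the species list (first-appearance order), the signed
#' stoichiometric matrix `nu` (species x steps, negative = consumed) and the
#' mass-action exponent matrices from a list of steps.
#'
#' @param steps list of steps; each a list with named numeric vectors
#'   `reactants` and `products` (stoichiometric counts; duplicate names
#'   accumulate) and rate constants `k_f`, `k_r` (`k_r = 0` for an
#'   irreversible step). [elementary_step()] objects with rates attached are
#'   also accepted via `k_f`/`k_r` elements.
#' @param compositions optional named list of element-count vectors; when
#'   given, every step is checked for element conservation.
#' @return an object of class `rxnkin_network` with `species`, `nu`,
#'   `react_order`, `prod_order`, `k_f`, `k_r`.
#' @export
build_network <- function(steps, compositions = NULL) {
  if (!length(steps)) {
    rxnkin_stop("rxnkin_domain_error", "build_network: no steps")
  }
  collapse <- function(v) {
    if (is.null(names(v)) || any(!nzchar(names(v)))) {
      rxnkin_stop("rxnkin_domain_error", "step sides must be named vectors")
    }
    tapply(as.numeric(v), names(v), sum)[unique(names(v))]
  }
  sides <- lapply(steps, function(s)
    list(r = collapse(s$reactants), p = collapse(s$products)))
  species <- unique(unlist(lapply(sides, function(s)
    c(names(s$r), names(s$p)))))
  n <- length(species); m <- length(steps)
  nu <- matrix(0, n, m, dimnames = list(species, NULL))
  react_order <- nu; prod_order <- nu
  for (j in seq_len(m)) {
    react_order[names(sides[[j]]$r), j] <- sides[[j]]$r
    prod_order[names(sides[[j]]$p), j] <- sides[[j]]$p
    nu[, j] <- prod_order[, j] - react_order[, j]
  }
  if (!is.null(compositions)) {
    for (j in seq_len(m)) {
      lhs <- sum_compositions(compositions[names(sides[[j]]$r)],
                              unname(sides[[j]]$r))
      rhs <- sum_compositions(compositions[names(sides[[j]]$p)],
                              unname(sides[[j]]$p))
      if (!same_composition(lhs, rhs)) {
        rxnkin_stop("rxnkin_composition_error", "step ", j,
                    " is not composition-balanced: ",
                    composition_imbalance_message(lhs, rhs))
      }
    }
  }
  k_f <- vapply(steps, function(s) as_rate_value(s$k_f), 0)
  k_r <- vapply(steps, function(s)
    if (is.null(s$k_r)) 0 else as_rate_value(s$k_r), 0)
  if (any(k_f < 0) || any(k_r < 0)) {
    rxnkin_stop("rxnkin_domain_error", "rate constants must be >= 0")
  }
  structure(list(species = species, nu = nu, react_order = react_order,
                 prod_order = prod_order, k_f = k_f, k_r = k_r),
            class = "rxnkin_network")
}

as_rate_value <- function(k) {
  if (inherits(k, "rxnkin_rate")) k$value else as.numeric(k)
}

#' @export
print.rxnkin_network <- function(x, ...) {
  cat("<kinetic network> ", length(x$species), " species, ",
      ncol(x$nu), " steps\n", sep = "")
  for (j in seq_len(ncol(x$nu))) {
    lhs <- x$react_order[, j]; rhs <- x$prod_order[, j]
    fmt <- function(v) paste(ifelse(v[v > 0] == 1, "",
                                    paste0(v[v > 0], " ")),
                             x$species[v > 0], sep = "", collapse = " + ")
    cat(sprintf("  %s %s %s   k_f = %.4g, k_r = %.4g\n", fmt(lhs),
                if (x$k_r[j] > 0) "<->" else "->", fmt(rhs),
                x$k_f[j], x$k_r[j]))
  }
  invisible(x)
}

#' Mass-action right-hand side of the network ODEs
#'
#' `rate_j = k_f_j * prod_i c_i^order_f - k_r_j * prod_i c_i^order_r`,
#' `dC/dt = nu %*% rate`.
#'
#' @param network a [build_network()] result.
#' @param conc concentration vector (ordered as `network$species`).
#' @return named vector dC/dt in mol L^-1 s^-1.
#' @export
network_rhs <- function(network, conc) {
  c_safe <- pmax(conc, 0)
  fwd <- network$k_f *
    apply(c_safe^network$react_order, 2, prod)
  rev <- network$k_r *
    apply(c_safe^network$prod_order, 2, prod)
  stats::setNames(as.numeric(network$nu %*% (fwd - rev)), network$species)
}

#' Define a microkinetic problem
#'
#' @param network a [build_network()] result.
#' @param c0 named initial concentrations in mol/L (species absent from the
#'   name set start at 0).
#' @param t_end end of the integration window in seconds.
#' @param times optional explicit output grid (must start at 0); default is
#'   0 plus a 200-point logarithmic grid up to `t_end`.
#' @param rtol,atol solver tolerances.
#' @param eq_tol equilibrium threshold on `max |dC/dt|` in mol L^-1 s^-1;
#'   default `1e-12 * max(c0)`.
#' @param T temperature label in K (bookkeeping only).
#' @return a list of class `rxnkin_problem`.
#' @export
mkm_problem <- function(network, c0, t_end, times = NULL,
                        rtol = 1e-8, atol = 1e-12, eq_tol = NULL,
                        T = NA_real_) {
  stopifnot(inherits(network, "rxnkin_network"))
  full_c0 <- stats::setNames(numeric(length(network$species)),
                             network$species)
  if (is.null(names(c0))) {
    stopifnot(length(c0) == length(full_c0))
    full_c0[] <- c0
  } else {
    unknown <- setdiff(names(c0), network$species)
    if (length(unknown)) {
      rxnkin_stop("rxnkin_domain_error", "c0 names not in network: ",
                  paste(unknown, collapse = ", "))
    }
    full_c0[names(c0)] <- c0
  }
  if (any(!is.finite(full_c0)) || any(full_c0 < 0)) {
    rxnkin_stop("rxnkin_domain_error", "c0 must be finite and non-negative")
  }
  if (t_end <= 0 || rtol <= 0 || atol <= 0) {
    rxnkin_stop("rxnkin_domain_error", "t_end and tolerances must be > 0")
  }
  if (is.null(eq_tol)) eq_tol <- 1e-12 * max(full_c0, 1e-300)
  if (is.null(times)) {
    times <- c(0, 10^seq(log10(t_end) - 9, log10(t_end), length.out = 200))
  }
  if (times[1] != 0) {
    rxnkin_stop("rxnkin_domain_error", "output grid must start at t = 0")
  }
  structure(list(network = network, c0 = full_c0, t_end = t_end,
                 times = times, rtol = rtol, atol = atol, eq_tol = eq_tol,
                 T = T),
            class = "rxnkin_problem")
}

#' Integrate a microkinetic problem
#'
#' Stiff-capable adaptive integration (lsoda, which switches between Adams
#' and BDF) of the mass-action ODE system. Equilibrium is detected when
#' `max |dC/dt| < eq_tol` is sustained over one output interval; small
#' negative undershoots (within `-atol`) are clipped to zero, larger ones
#' clipped with a warning.
#'
#' @param problem a [mkm_problem()].
#' @return an object of class `rxnkin_mkm_result` with `times`, `conc`
#'   (time x species matrix), `reached_equilibrium`, `equilibrium_time`,
#'   `conserved_residual`.
#' @export
simulate_network <- function(problem) {
  stopifnot(inherits(problem, "rxnkin_problem"))
  net <- problem$network
  f <- function(t, y, parms) list(network_rhs(net, y))
  sol <- try(deSolve::ode(y = problem$c0, times = problem$times, func = f,
                          parms = NULL, method = "lsoda",
                          rtol = problem$rtol, atol = problem$atol),
             silent = TRUE)
  if (inherits(sol, "try-error") ||
      nrow(sol) < length(problem$times)) {
    last <- if (inherits(sol, "try-error")) problem$c0 else sol[nrow(sol), -1]
    cond <- structure(
      class = c("rxnkin_solver_error", "rxnkin_error", "error", "condition"),
      list(message = "ODE integration failed before t_end",
           call = sys.call(), last_state = last))
    stop(cond)
  }
  times <- sol[, 1]
  conc <- sol[, -1, drop = FALSE]
  colnames(conc) <- net$species
  if (any(conc < -problem$atol)) {
    warning("concentration undershoot below -atol clipped to zero",
            call. = FALSE)
  }
  conc[conc < 0] <- 0

  dnorm_inf <- apply(conc, 1, function(cc) max(abs(network_rhs(net, cc))))
  eq_idx <- which(dnorm_inf < problem$eq_tol)
  sustained <- eq_idx[eq_idx < nrow(conc) & (eq_idx + 1L) %in% eq_idx]
  reached <- length(sustained) > 0
  eq_time <- if (reached) times[sustained[1]] else NA_real_

  L <- conserved_moieties(net)
  resid <- 0
  if (ncol(L)) {
    q0 <- as.numeric(problem$c0 %*% L)
    qt <- conc %*% L
    scale <- pmax(abs(q0), 1e-300)
    resid <- max(abs(sweep(qt, 2, q0)) / rep(scale, each = nrow(qt)))
  }
  structure(list(times = times, conc = conc,
                 reached_equilibrium = reached, equilibrium_time = eq_time,
                 conserved_residual = resid, problem = problem),
            class = "rxnkin_mkm_result")
}

#' @export
print.rxnkin_mkm_result <- function(x, ...) {
  cat("<microkinetic result> ", length(x$times), " time points to t = ",
      format(max(x$times)), " s\n", sep = "")
  cat("  equilibrium: ",
      if (x$reached_equilibrium) sprintf("reached at t = %g s",
                                         x$equilibrium_time) else
        "not reached", "\n", sep = "")
  cat(sprintf("  conserved-moiety drift: %.3g (relative)\n",
              x$conserved_residual))
  final <- x$conc[nrow(x$conc), ]
  cat("  final concentrations (mol/L):\n")
  for (s in names(final)) cat(sprintf("    %-12s %.6g\n", s, final[s]))
  invisible(x)
}

# ---- exact left null space -----------------------------------------------

# Exact Gauss-Jordan elimination over the rationals for small integer
# matrices; rationals carried as numerator/denominator pairs. Returns the
# null space basis of A (columns), denominators cleared to integers.
rational_nullspace <- function(A) {
  m <- nrow(A); n <- ncol(A)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  if (m == 0) return(diag(1, n))
  num <- matrix(as.numeric(A), m, n)
  den <- matrix(1, m, n)
  gcd2 <- function(a, b) {
    a <- abs(a); b <- abs(b)
    while (b > 0.5) { t <- b; b <- a %% b; a <- t }
    max(a, 1)
  }
  norm_rat <- function(p, q) {
    if (q < 0) { p <- -p; q <- -q }
    g <- gcd2(p, q)
    c(p / g, q / g)
  }
  pivots <- integer(0); pivot_rows <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    sel <- which(num[row:m, col] != 0)
    if (!length(sel)) next
    sel <- row + sel[1] - 1L
    if (sel != row) {
      num[c(row, sel), ] <- num[c(sel, row), ]
      den[c(row, sel), ] <- den[c(sel, row), ]
    }
    # scale pivot row to 1 at (row, col)
    p <- num[row, col]; q <- den[row, col]
    for (k in seq_len(n)) {
      r <- norm_rat(num[row, k] * q, den[row, k] * p)
      num[row, k] <- r[1]; den[row, k] <- r[2]
    }
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      fp <- num[i, col]; fq <- den[i, col]
      for (k in seq_len(n)) {
        # a_ik <- a_ik - f * a_row,k
        p1 <- num[i, k]; q1 <- den[i, k]
        p2 <- fp * num[row, k]; q2 <- fq * den[row, k]
        r <- norm_rat(p1 * q2 - p2 * q1, q1 * q2)
        num[i, k] <- r[1]; den[i, k] <- r[2]
      }
    }
    pivots <- c(pivots, col); pivot_rows <- c(pivot_rows, row)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  if (!length(free)) return(matrix(numeric(0), n, 0))
  basis <- matrix(0, n, length(free))
  for (j in seq_along(free)) {
    fc <- free[j]
    x_num <- numeric(n); x_den <- rep(1, n)
    x_num[fc] <- 1
    for (i in seq_along(pivots)) {
      x_num[pivots[i]] <- -num[pivot_rows[i], fc]
      x_den[pivots[i]] <- den[pivot_rows[i], fc]
    }
    lcm_all <- 1
    for (i in seq_len(n)) lcm_all <- lcm_all / gcd2(lcm_all, x_den[i]) * x_den[i]
    v <- x_num * (lcm_all / x_den)
    g <- 0
    for (i in seq_len(n)) if (v[i] != 0) g <- gcd2(g, v[i])
    if (g > 1) v <- v / g
    basis[, j] <- v
  }
  basis
}

#' Conserved moieties of a kinetic network
#'
#' Basis of the left null space of the stoichiometric matrix, computed by
#' exact rational elimination; each column `l` satisfies
#' `t(l) %*% nu == 0`, so `sum(l * conc)` is invariant along any
#' trajectory.
#'
#' @param network a [build_network()] result.
#' @return numeric matrix (species x moieties) with integer entries; zero
#'   columns mean no conservation law.
#' @export
conserved_moieties <- function(network) {
  # left null space of nu = null space of t(nu)
  L <- rational_nullspace(t(network$nu))
  rownames(L) <- network$species
  L
}

#' Selectivity toward a target product
#'
#' `S = c_target / (c_target + sum c_competitors)` evaluated at the
#' detected equilibrium time, or at `t_end` (with a warning) when
#' equilibrium was not reached and `force = TRUE`.
#'
#' @param result a [simulate_network()] result.
#' @param target product species name.
#' @param competitors character vector of competing product names.
#' @param force evaluate at t_end even without detected equilibrium.
#' @return selectivity fraction in `[0, 1]`.
#' @export
selectivity <- function(result, target, competitors, force = FALSE) {
  stopifnot(inherits(result, "rxnkin_mkm_result"))
  if (!result$reached_equilibrium) {
    if (!force) {
      rxnkin_stop("rxnkin_state_error",
                  "system did not reach equilibrium; ",
                  "use force = TRUE to evaluate at t_end")
    }
    warning("evaluating selectivity at t_end without detected equilibrium",
            call. = FALSE)
  }
  idx <- if (result$reached_equilibrium) {
    which(result$times == result$equilibrium_time)[1]
  } else nrow(result$conc)
  cc <- result$conc[idx, ]
  ct <- cc[target]
  comp <- sum(cc[competitors])
  if (!is.finite(ct + comp) || ct + comp <= 0) {
    rxnkin_stop("rxnkin_selectivity_error",
                "all product concentrations are zero; selectivity undefined")
  }
  as.numeric(ct / (ct + comp))
}

# initial rate of `species` from the earliest window with <= conversion_max
# conversion of the limiting reactant (finite difference over the window)
initial_rate <- function(problem, species, conversion_max = 0.05) {
  net <- problem$network
  r0 <- network_rhs(net, problem$c0)
  consumed <- names(r0)[r0 < 0 & problem$c0 > 0]
  if (!length(consumed)) {
    return(abs(r0[species]))
  }
  dt_lim <- min(conversion_max * problem$c0[consumed] / abs(r0[consumed]))
  dt <- min(dt_lim, problem$t_end)
  p_win <- mkm_problem(net, problem$c0, t_end = dt,
                       times = seq(0, dt, length.out = 21),
                       rtol = problem$rtol, atol = problem$atol,
                       T = problem$T)
  sim <- simulate_network(p_win)
  nT <- nrow(sim$conc)
  abs(sim$conc[nT, species] - sim$conc[1, species]) / dt
}

#' Apparent activation energy from simulations at several temperatures
#'
#' Runs one microkinetic simulation per temperature, measures the initial
#' rate of the probe species over the earliest window with at most
#' `conversion_max` conversion of the limiting reactant, and fits
#' `ln r = a + b * (1/T)` by least squares; `Ea = -R * b`.
#'
#' @param problem_factory function `T -> mkm_problem`.
#' @param temperatures numeric vector of at least 2 temperatures in K.
#' @param species probe species name (rate of formation or consumption).
#' @param conversion_max conversion cap defining the initial-rate window.
#' @return a list of class `rxnkin_arrhenius_fit` with `ea_apparent`
#'   (kcal/mol), `intercept` (ln A), `r_squared` and the per-point `data`.
#' @export
apparent_activation_energy <- function(problem_factory, temperatures,
                                       species, conversion_max = 0.05) {
  if (length(temperatures) < 2) {
    rxnkin_stop("rxnkin_domain_error", "need at least 2 temperatures")
  }
  rates <- vapply(temperatures, function(T) {
    initial_rate(problem_factory(T), species, conversion_max)
  }, 0)
  if (any(rates <= 0)) {
    rxnkin_stop("rxnkin_fit_error",
                "non-positive probe rate at T = ",
                paste(temperatures[rates <= 0], collapse = ", "), " K")
  }
  fit <- stats::lm(log(rates) ~ I(1 / temperatures))
  structure(list(
    ea_apparent = -R_KCAL * stats::coef(fit)[[2]],
    intercept = stats::coef(fit)[[1]],
    r_squared = suppressWarnings(summary(fit)$r.squared),
    data = data.frame(T = temperatures, rate = rates)
  ), class = "rxnkin_arrhenius_fit")
}

#' @export
print.rxnkin_arrhenius_fit <- function(x, ...) {
  cat(sprintf("<Arrhenius fit> Ea(apparent) = %.4f kcal/mol | ln A = %.4f | R^2 = %.6f\n",
              x$ea_apparent, x$intercept, x$r_squared))
  invisible(x)
}

#' Reaction order from simulations at several initial concentrations
#'
#' Measures the initial rate of the probe species for each starting
#' concentration and fits `ln r = a + n * ln c0`; the slope `n` is the
#' apparent reaction order.
#'
#' @param problem_factory function `c0 -> mkm_problem` (scalar c0 of the
#'   varied reactant).
#' @param initial_concs numeric vector of at least 2 positive
#'   concentrations.
#' @param species probe species name.
#' @param conversion_max conversion cap defining the initial-rate window.
#' @return a list of class `rxnkin_order_fit` with `order`, `intercept`,
#'   `r_squared` and the per-point `data`.
#' @export
reaction_order <- function(problem_factory, initial_concs, species,
                           conversion_max = 0.05) {
  if (length(initial_concs) < 2) {
    rxnkin_stop("rxnkin_domain_error", "need at least 2 concentrations")
  }
  if (any(initial_concs <= 0)) {
    rxnkin_stop("rxnkin_domain_error", "initial concentrations must be > 0")
  }
  rates <- vapply(initial_concs, function(c0) {
    initial_rate(problem_factory(c0), species, conversion_max)
  }, 0)
  if (any(rates <= 0)) {
    rxnkin_stop("rxnkin_fit_error", "non-positive probe rate")
  }
  fit <- stats::lm(log(rates) ~ log(initial_concs))
  structure(list(
    order = stats::coef(fit)[[2]],
    intercept = stats::coef(fit)[[1]],
    r_squared = suppressWarnings(summary(fit)$r.squared),
    data = data.frame(c0 = initial_concs, rate = rates)
  ), class = "rxnkin_order_fit")
}

#' @export
print.rxnkin_order_fit <- function(x, ...) {
  cat(sprintf("<order fit> apparent order = %.4f | R^2 = %.6f\n",
              x$order, x$r_squared))
  invisible(x)
}
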