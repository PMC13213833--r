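test_that("stoichiometric matrix assembly follows first-appearance order", {
  net <- build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                                 k_f = 1, k_r = 0)))
  expect_identical(net$species, c("A", "B"))
  expect_identical(as.numeric(net$nu), c(-1, 1))
  net2 <- build_network(list(list(reactants = c(A = 1, B = 1),
                                  products = c(C = 1), k_f = 1, k_r = 0)))
  expect_identical(as.numeric(net2$nu), c(-1, -1, 1))
  # duplicate names within one side accumulate
  net3 <- build_network(list(list(reactants = c(A = 1, A = 1),
                                  products = c(B = 1), k_f = 1, k_r = 0)))
  expect_identical(unname(net3$nu["A", 1]), -2)
  expect_identical(unname(net3$react_order["A", 1]), 2)
  # composition balance is enforced when compositions are supplied
  expect_error(
    build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                            k_f = 1, k_r = 0)),
                  compositions = list(A = c(C = 1L), B = c(C = 2L))),
    class = "rxnkin_composition_error")
})

test_that("mass-action right-hand side: arithmetic, zeros, equilibrium fixed point", {
  net <- build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                                 k_f = 2, k_r = 0)))
  expect_equal(network_rhs(net, c(0.5, 0)), c(A = -1, B = 1))
  net0 <- build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                                  k_f = 0, k_r = 0)))
  expect_equal(network_rhs(net0, c(1, 1)), c(A = 0, B = 0))
  rev <- build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                                 k_f = 2, k_r = 1)))
  expect_equal(network_rhs(rev, c(1, 2)), c(A = 0, B = 0))  # c_B/c_A = k_f/k_r
})

test_that("exponential decay matches the closed form within solver tolerance", {
  fx <- make_first_order_network(k = 1, c0 = 1, t_end = 5)
  res <- simulate_network(fx$problem)
  expect_equal(unname(res$conc[1, "A"]), 1)
  expect_equal(unname(res$conc[, "A"]), fx$closed_form(res$times),
               tolerance = 1e-6)
  # value at t = 1 s specifically
  p <- mkm_problem(fx$problem$network, c(A = 1), t_end = 1,
                   times = c(0, 0.5, 1))
  r2 <- simulate_network(p)
  expect_equal(unname(r2$conc[3, "A"]), exp(-1), tolerance = 1e-7)
})

test_that("reversible A<->B equilibrates to k_f/k_r and is detected", {
  net <- build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                                 k_f = 2, k_r = 1)))
  res <- simulate_network(mkm_problem(net, c(A = 1), t_end = 50))
  expect_true(res$reached_equilibrium)
  final <- res$conc[nrow(res$conc), ]
  expect_equal(unname(final["A"]), 1 / 3, tolerance = 1e-6)
  expect_equal(unname(final["B"] / final["A"]), 2, tolerance = 1e-6)
})

test_that("zero-rate networks stay constant", {
  net <- build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                                 k_f = 0, k_r = 0)))
  res <- simulate_network(mkm_problem(net, c(A = 0.7, B = 0.2), t_end = 10))
  expect_true(all(res$conc[, "A"] == 0.7))
  expect_true(all(res$conc[, "B"] == 0.2))
})

test_that("conserved moieties: exact left-null-space bases", {
  net <- build_network(list(list(reactants = c(A = 1), products = c(B = 1),
                                 k_f = 1, k_r = 0)))
  L <- conserved_moieties(net)
  expect_identical(dim(L), c(2L, 1L))
  expect_equal(as.numeric(L[, 1] / L[1, 1]), c(1, 1))
  net2 <- build_network(list(list(reactants = c(A = 1, B = 1),
                                  products = c(C = 1), k_f = 1, k_r = 0)))
  L2 <- conserved_moieties(net2)
  expect_identical(ncol(L2), 2L)
  expect_true(all(abs(t(L2) %*% net2$nu) < 1e-12))
  # independent SVD oracle spans the same space
  sv <- svd(t(net2$nu), nv = 3)
  null_svd <- sv$v[, 2:3]   # rank of a single step is 1 -> 2D null space
  proj <- null_svd %*% t(null_svd)
  expect_equal(unname(proj %*% L2), unname(L2), tolerance = 1e-9)
})

test_that("randomized linear networks match the matrix-exponential oracle", {
  set.seed(101)
  for (trial in 1:5) {
    n <- sample(2:5, 1)
    steps <- list()
    for (i in seq_len(n - 1)) {
      steps[[length(steps) + 1L]] <- list(
        reactants = stats::setNames(1, paste0("S", i)),
        products = stats::setNames(1, paste0("S", i + 1)),
        k_f = runif(1, 0.1, 5), k_r = runif(1, 0, 2))
    }
    net <- build_network(steps)
    c0 <- stats::setNames(runif(n, 0, 2), net$species)
    # rate-constant matrix for the closed form c(t) = expm(K t) c0,
    # assembled independently of the mass-action RHS
    K <- matrix(0, n, n, dimnames = list(net$species, net$species))
    for (j in seq_along(steps)) {
      r <- names(steps[[j]]$reactants); p <- names(steps[[j]]$products)
      K[p, r] <- K[p, r] + steps[[j]]$k_f
      K[r, r] <- K[r, r] - steps[[j]]$k_f
      K[r, p] <- K[r, p] + steps[[j]]$k_r
      K[p, p] <- K[p, p] - steps[[j]]$k_r
    }
    t_probe <- c(0.3, 1.5)
    res <- simulate_network(mkm_problem(net, c0, t_end = 1.5,
                                        times = c(0, t_probe)))
    for (ti in seq_along(t_probe)) {
      oracle <- as.numeric(Matrix::expm(K * t_probe[ti]) %*% c0)
      expect_equal(unname(res$conc[ti + 1, ]), oracle, tolerance = 1e-6)
    }
    expect_lt(res$conserved_residual, 1e-6)
  }
})

test_that("conserved moieties drift below 1e-6 in a stiff bimolecular network", {
  net <- build_network(list(
    list(reactants = c(A = 1, B = 1), products = c(C = 1),
         k_f = 1e6, k_r = 1e-3),
    list(reactants = c(C = 1), products = c(D = 1), k_f = 1e-2, k_r = 0)))
  res <- simulate_network(mkm_problem(net, c(A = 1, B = 0.5), t_end = 1e3))
  expect_lt(res$conserved_residual, 1e-6)
})

test_that("selectivity of competing first-order channels equals k1/(k1+k2)", {
  net <- build_network(list(
    list(reactants = c(A = 1), products = c(B = 1), k_f = 3, k_r = 0),
    list(reactants = c(A = 1), products = c(C = 1), k_f = 1, k_r = 0)))
  res <- simulate_network(mkm_problem(net, c(A = 1), t_end = 20))
  expect_true(res$reached_equilibrium)
  expect_equal(selectivity(res, "B", "C"), 0.75, tolerance = 1e-6)
  # single product, no competitors
  expect_equal(selectivity(res, "B", character(0)), 1.0)
  # independence of evaluation time: force evaluation mid-course
  early <- simulate_network(mkm_problem(net, c(A = 1), t_end = 0.05))
  expect_warning(s_early <- selectivity(early, "B", "C", force = TRUE))
  expect_equal(s_early, 0.75, tolerance = 1e-6)
  # all products zero -> undefined
  none <- simulate_network(mkm_problem(net, c(A = 0), t_end = 1))
  expect_error(selectivity(none, "B", "C"),
               class = "rxnkin_selectivity_error")
})

test_that("apparent Ea: zero for T-independent rates, dH + RT for one Eyring step", {
  # T-independent rate constants -> Ea = 0
  factory0 <- function(T) {
    net <- build_network(list(list(reactants = c(A = 1),
                                   products = c(B = 1), k_f = 2, k_r = 0)))
    mkm_problem(net, c(A = 1), t_end = 10, T = T)
  }
  fit0 <- apparent_activation_energy(factory0, c(350, 375, 400), "A")
  expect_lt(abs(fit0$ea_apparent), 1e-6)

  # single unimolecular Eyring step with dH_act = 10 kcal/mol, dS_act = 0:
  # Ea = dH_act + R*Tbar
  dH <- 10
  factory <- function(T) {
    k <- eyring_rate(dH, T)$value   # dG(T) = dH since dS = 0
    net <- build_network(list(list(reactants = c(A = 1),
                                   products = c(B = 1), k_f = k, k_r = 0)))
    mkm_problem(net, c(A = 1), t_end = 1 / k, T = T)
  }
  Ts <- seq(350, 400, by = 10)
  fit <- apparent_activation_energy(factory, Ts, "A")
  R_kcal <- physical_constants$R / 4.184 / 1000
  expect_equal(fit$ea_apparent, dH + R_kcal * mean(Ts), tolerance = 0.02)
  expect_gt(fit$r_squared, 0.9999)
  expect_error(apparent_activation_energy(factory, 350, "A"),
               class = "rxnkin_domain_error")
})

test_that("two-step sequence: apparent Ea tracks the rate-determining step", {
  # step 1 slow (Ea1 = 20), step 2 fast (Ea2 = 5): apparent Ea ~ step 1 slope
  factory <- function(T) {
    k1 <- eyring_rate(20, T)$value
    k2 <- eyring_rate(5, T)$value
    net <- build_network(list(
      list(reactants = c(A = 1), products = c(I = 1), k_f = k1, k_r = 0),
      list(reactants = c(I = 1), products = c(P = 1), k_f = k2, k_r = 0)))
    mkm_problem(net, c(A = 1), t_end = 0.1 / k1, T = T)
  }
  Ts <- seq(350, 400, by = 10)
  fit <- apparent_activation_energy(factory, Ts, "A")
  R_kcal <- physical_constants$R / 4.184 / 1000
  expect_equal(fit$ea_apparent, 20 + R_kcal * mean(Ts), tolerance = 0.1)
})

test_that("reaction orders 1 and 2 are recovered from first/second-order toys", {
  factory1 <- function(c0) {
    net <- build_network(list(list(reactants = c(A = 1),
                                   products = c(B = 1), k_f = 0.7, k_r = 0)))
    mkm_problem(net, c(A = c0), t_end = 50)
  }
  fit1 <- reaction_order(factory1, c(0.25, 0.5, 1, 2), "A")
  expect_equal(fit1$order, 1.0, tolerance = 1e-4)

  factory2 <- function(c0) {
    net <- build_network(list(list(reactants = c(A = 2),
                                   products = c(B = 1), k_f = 0.3, k_r = 0)))
    mkm_problem(net, c(A = c0), t_end = 50)
  }
  fit2 <- reaction_order(factory2, c(0.25, 0.5, 1, 2), "A")
  expect_equal(fit2$order, 2.0, tolerance = 1e-3)
  expect_error(reaction_order(factory1, c(-1, 1), "A"),
               class = "rxnkin_domain_error")
})

test_that("saturated two-step toy shows near-zero apparent order", {
  # A + S <-> AS (fast, strong binding, S scarce), AS -> P + S (slow):
  # at large c0(A) the probe rate saturates -> order ~ 0
  factory <- function(c0) {
    net <- build_network(list(
      list(reactants = c(A = 1, S = 1), products = c(AS = 1),
           k_f = 1e6, k_r = 1e-2),
      list(reactants = c(AS = 1), products = c(P = 1, S = 1),
           k_f = 1, k_r = 0)))
    mkm_problem(net, c(A = c0, S = 1e-3), t_end = 10)
  }
  fit <- reaction_order(factory, c(10, 20, 40), "P")
  expect_lt(abs(fit$order), 0.05)
})
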