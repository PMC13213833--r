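test_that("zero-point energy matches the closed form and skips imaginary modes", {
  expect_identical(zero_point_energy(numeric(0)), 0)
  # NA*h*c*nu/2 for 1000 cm^-1, computed independently
  expect_equal(zero_point_energy(1000), 1.4295717691, tolerance = 1e-9)
  expect_identical(zero_point_energy(c(-500, 1000)),
                   zero_point_energy(1000))
  # scaling all frequencies by s scales ZPE by exactly s
  freqs <- c(120.5, 800, 1650.2, 3000)
  expect_equal(zero_point_energy(freqs, scale = 0.97),
               0.97 * zero_point_energy(freqs), tolerance = 1e-12)
})

test_that("translational entropy reproduces Sackur-Tetrode", {
  # Ar, 298.15 K, 1 bar: 154.8457 J/mol/K, evaluated independently
  s <- translational_entropy(39.948, 298.15, 1e5)
  expect_equal(s * 4.184, 154.84565973, tolerance = 1e-6)
  # analytic identity S(2T) - S(T) = (5/2) R ln 2
  d <- translational_entropy(39.948, 2 * 298.15, 1e5) - s
  expect_equal(d, 2.5 * physical_constants$R_cal * log(2), tolerance = 1e-10)
  expect_error(translational_entropy(0, 298.15), class = "rxnkin_domain_error")
  expect_error(translational_entropy(1, -5), class = "rxnkin_domain_error")
})

test_that("Sackur-Tetrode closed form holds for randomized mass/T/P", {
  set.seed(42)
  pc <- physical_constants
  for (i in 1:20) {
    mass <- runif(1, 1, 300); T <- runif(1, 50, 2000); P <- runif(1, 1e3, 1e7)
    m <- mass * pc$amu
    expected <- pc$R_cal *
      (log((2 * pi * m * pc$kB * T / pc$h^2)^1.5 * pc$kB * T / P) + 2.5)
    expect_equal(translational_entropy(mass, T, P), expected,
                 tolerance = 1e-6)
  }
})

test_that("rotational entropy: monoatomic zero, sigma identity, linear closed form", {
  ar <- geometry("Ar", matrix(0, 1, 3))
  expect_identical(rotational_entropy(ar, 1, 298.15), 0)
  # homonuclear diatomic at 1.1 A, sigma 2: hand-evaluated q = T/(sigma*theta)
  n2 <- geometry(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  expect_true(is_linear_geometry(n2))
  expect_equal(rotational_entropy(n2, sigma = 2, T = 298.15),
               9.8418335821, tolerance = 1e-8)
  # doubling sigma lowers S by exactly R ln 2
  h2o <- geometry(c("O", "H", "H"),
                  rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                        c(0, -0.7572, -0.4692)))
  expect_false(is_linear_geometry(h2o))
  expect_equal(rotational_entropy(h2o, 1, 298.15) -
                 rotational_entropy(h2o, 2, 298.15),
               physical_constants$R_cal * log(2), tolerance = 1e-10)
  expect_error(rotational_entropy(h2o, 0, 298.15),
               class = "rxnkin_domain_error")
  degenerate <- geometry(c("C", "C", "C"), matrix(0, 3, 3))
  expect_error(rotational_entropy(degenerate, 1, 298.15),
               class = "rxnkin_geometry_error")
})

test_that("vibrational thermo matches the harmonic closed form and limits", {
  expect_equal(vibrational_thermo(numeric(0), 298.15),
               list(e_vib = 0, s_vib = 0))
  v <- vibrational_thermo(100, 298.15)
  expect_equal(v$s_vib * 4.184, 14.45286428, tolerance = 1e-6)
  expect_equal(v$e_vib, 0.4609811566, tolerance = 1e-8)
  # high-frequency limit: both vanish
  hi <- vibrational_thermo(1e5, 298.15)
  expect_lt(hi$e_vib, 1e-200)
  expect_lt(hi$s_vib, 1e-200)
  # imaginary modes excluded
  expect_equal(vibrational_thermo(c(-300, 100), 298.15), v)
})

test_that("low-frequency treatments floor and qrrho raise only low-mode entropy", {
  plain <- vibrational_thermo(c(30, 500, 2000), 298.15)
  floored <- vibrational_thermo(c(30, 500, 2000), 298.15,
                                treatment = "floor", nu0 = 100)
  qr <- vibrational_thermo(c(30, 500, 2000), 298.15,
                           treatment = "qrrho", nu0 = 100)
  # entropy-only corrections: thermal energy untouched
  expect_identical(floored$e_vib, plain$e_vib)
  expect_identical(qr$e_vib, plain$e_vib)
  expect_lt(floored$s_vib, plain$s_vib)     # 30 cm^-1 floored to 100
  expect_lt(qr$s_vib, plain$s_vib)
  # modes above nu0 are essentially untouched by qrrho
  hi_only <- vibrational_thermo(2000, 298.15, treatment = "qrrho")
  expect_lt(abs(hi_only$s_vib - vibrational_thermo(2000, 298.15)$s_vib),
            1e-4)
})

test_that("electronic entropy is R ln(multiplicity)", {
  expect_identical(electronic_entropy(1), 0)
  expect_equal(electronic_entropy(2) * 4.184, 5.7631463216,
               tolerance = 1e-8)
  expect_error(electronic_entropy(0), class = "rxnkin_domain_error")
})

test_that("monoatomic assembly: H = E_elec + (5/2)RT and S = S_trans + S_elec", {
  pc <- physical_constants
  rec <- qc_record(-1.0, geometry("Ar", matrix(0, 1, 3)))
  cond <- thermo_conditions(T = 298.15, standard_state = "gas_1bar")
  th <- thermochemistry(rec, cond)
  RT <- pc$R * 298.15 / 4.184 / 1000
  expect_equal(th$enthalpy, -1.0 * pc$hartree_to_kcal + 2.5 * RT,
               tolerance = 1e-10)
  expect_equal(th$entropy_total, translational_entropy(39.9623831225,
                                                       298.15, 1e5),
               tolerance = 1e-10)
  expect_identical(th$s_rot, 0)
  expect_identical(th$s_vib, 0)
})

test_that("G = H - T*S identity holds on randomized records", {
  for (seed in 1:15) {
    sp <- make_species(seed, role = if (seed %% 4 == 0) "transition_state"
                       else "minimum")
    rec <- qc_record(sp$electronic_energy, sp$geometry, sp$frequencies,
                     sp$multiplicity)
    T <- 250 + 20 * seed
    th <- thermochemistry(rec, thermo_conditions(T = T), validate = FALSE)
    expect_equal(th$gibbs, th$enthalpy - T * th$entropy_total / 1000,
                 tolerance = 1e-9)
    expect_equal(th$entropy_total,
                 th$s_trans + th$s_rot + th$s_vib + th$s_elec,
                 tolerance = 1e-12)
  }
})

test_that("transition-state records drop the imaginary mode; 2+ imaginary rejected", {
  ts <- make_species(7, role = "transition_state")
  rec <- qc_record(ts$electronic_energy, ts$geometry, ts$frequencies)
  th_ts <- thermochemistry(rec, thermo_conditions())
  rec_real <- qc_record(ts$electronic_energy, ts$geometry,
                        ts$frequencies[ts$frequencies > 0])
  th_real <- thermochemistry(rec_real, thermo_conditions())
  expect_equal(th_ts$gibbs, th_real$gibbs, tolerance = 1e-12)
  rec_bad <- qc_record(-1, ts$geometry, c(-500, -300, 1000))
  expect_error(thermochemistry(rec_bad, thermo_conditions()),
               class = "rxnkin_validation_error")
  expect_s3_class(thermochemistry(rec_bad, thermo_conditions(),
                                  validate = FALSE), "rxnkin_thermo")
})

test_that("ZPE and vibrational sums grow monotonically with added modes", {
  modes <- c(150, 700, 1200, 2900)
  zpes <- vapply(seq_along(modes),
                 function(k) zero_point_energy(modes[1:k]), 0)
  expect_true(all(diff(zpes) > 0))
  svs <- vapply(seq_along(modes), function(k)
    vibrational_thermo(modes[1:k], 298.15)$s_vib, 0)
  expect_true(all(diff(svs) > 0))
})
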