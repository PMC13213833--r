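#' Thermochemical conditions
#'
#' Temperature, pressure, frequency scaling and the low-frequency entropy
#' treatment used by [thermochemistry()].
#'
#' @param T temperature in K.
#' @param P pressure in Pa.
#' @param frequency_scale multiplicative scale factor applied to all
#'   wavenumbers (default 1).
#' @param low_freq_treatment `"none"` (plain RRHO), `"floor"` (modes below
#'   `nu0` replaced by `nu0` in the entropy only), or `"qrrho"`
#'   (harmonic/free-rotor interpolation with a damping function
#'   `w = 1/(1 + (nu0/nu)^4)`).
#' @param nu0 low-frequency threshold in cm^-1 for `"floor"`/`"qrrho"`.
#' @param standard_state `"gas_1atm"`, `"gas_1bar"` or `"solution_1M"`;
#'   controls the pressure (or effective pressure `C0*R*T`) entering the
#'   translational entropy.
#' @return a list of class `rxnkin_conditions`.
#' @export
thermo_conditions <- function(T = 298.15, P = 101325,
                              frequency_scale = 1,
                              low_freq_treatment = c("none", "floor", "qrrho"),
                              nu0 = 100,
                              standard_state = c("gas_1atm", "gas_1bar",
                                                 "solution_1M")) {
  low_freq_treatment <- match.arg(low_freq_treatment)
  standard_state <- match.arg(standard_state)
  if (T <= 0 || P <= 0 || frequency_scale <= 0 || nu0 < 0) {
    rxnkin_stop("rxnkin_domain_error",
                "require T > 0, P > 0, frequency_scale > 0, nu0 >= 0")
  }
  structure(list(T = T, P = P, frequency_scale = frequency_scale,
                 low_freq_treatment = low_freq_treatment, nu0 = nu0,
                 standard_state = standard_state),
            class = "rxnkin_conditions")
}

# pressure used inside Sackur-Tetrode for the chosen standard state
effective_pressure <- function(conditions) {
  switch(conditions$standard_state,
         gas_1atm = 101325,
         gas_1bar = 1e5,
         # 1 M = 1000 mol/m^3 ideal gas: P_eff = C0 * R * T
         solution_1M = 1000 * physical_constants$R * conditions$T)
}

#' Zero-point vibrational energy
#'
#' `ZPE = sum_i NA*h*c*(scale*nu_i)/2` over real (positive) modes; imaginary
#' modes (negative wavenumbers) are excluded.
#'
#' @param frequencies wavenumbers in cm^-1.
#' @param scale frequency scale factor.
#' @return ZPE in kcal/mol.
#' @export
zero_point_energy <- function(frequencies, scale = 1) {
  pc <- physical_constants
  nu <- frequencies[frequencies > 0] * scale
  sum(pc$`NA` * pc$h * pc$c * nu / 2) / pc$cal_to_J / 1000
}

#' Translational entropy (Sackur-Tetrode)
#'
#' `S = R * (ln((2*pi*m*kB*T/h^2)^(3/2) * kB*T/P) + 5/2)` for an ideal gas.
#'
#' @param mass molecular mass in amu.
#' @param T temperature in K.
#' @param P pressure in Pa.
#' @return entropy in cal mol^-1 K^-1.
#' @export
translational_entropy <- function(mass, T, P = 101325) {
  if (mass <= 0 || T <= 0 || P <= 0) {
    rxnkin_stop("rxnkin_domain_error",
                "translational_entropy requires mass, T, P > 0")
  }
  pc <- physical_constants
  m <- mass * pc$amu
  q <- (2 * pi * m * pc$kB * T / pc$h^2)^1.5 * pc$kB * T / P
  pc$R_cal * (log(q) + 2.5)
}

# principal moments of inertia in amu*Angstrom^2
moments_of_inertia <- function(geom) {
  m <- atomic_mass(geom$elements)
  xyz <- geom$coordinates
  com <- colSums(xyz * m) / sum(m)
  xyz <- sweep(xyz, 2, com)
  r2 <- rowSums(xyz^2)
  I <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(m * ((a == b) * r2 - xyz[, a] * xyz[, b]))
  }
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Test whether a geometry is a linear rotor
#'
#' Uses moment-of-inertia degeneracy: the smallest principal moment must be
#' below `tol` while the other two are equal within `tol`.
#'
#' @param geom a [geometry()].
#' @param tol tolerance in amu Angstrom^2.
#' @return logical.
#' @export
is_linear_geometry <- function(geom, tol = 1e-6) {
  n <- length(geom$elements)
  if (n <= 1) return(FALSE)
  if (n == 2) return(TRUE)
  I <- moments_of_inertia(geom)
  I[1] < tol && abs(I[2] - I[3]) < tol * max(1, I[3])
}

#' Rotational entropy of a rigid rotor
#'
#' Monoatomics contribute zero. Linear rotors use `q = T/(sigma*theta_r)`
#' and `S = R*(ln q + 1)`; nonlinear rotors use
#' `q = (sqrt(pi)/sigma) * (T^3/(theta_A*theta_B*theta_C))^(1/2)` and
#' `S = R*(ln q + 3/2)`, with rotational temperatures from the principal
#' moments of inertia and pinned atomic masses.
#'
#' @param geom a [geometry()] with at least one atom.
#' @param sigma rotational symmetry number, integer >= 1.
#' @param T temperature in K.
#' @param linear logical or NA; NA infers linearity from the geometry.
#' @return entropy in cal mol^-1 K^-1.
#' @export
rotational_entropy <- function(geom, sigma = 1, T = 298.15, linear = NA) {
  if (sigma < 1) {
    rxnkin_stop("rxnkin_domain_error", "symmetry number must be >= 1")
  }
  if (T <= 0) rxnkin_stop("rxnkin_domain_error", "T must be > 0")
  n <- length(geom$elements)
  if (n == 0) rxnkin_stop("rxnkin_geometry_error", "empty geometry")
  if (n == 1) return(0)
  if (is.na(linear)) linear <- is_linear_geometry(geom)
  pc <- physical_constants
  I_amu <- moments_of_inertia(geom)                # amu Angstrom^2
  I <- I_amu * pc$amu * 1e-20                      # kg m^2
  theta <- pc$h^2 / (8 * pi^2 * I * pc$kB)         # rotational temperatures
  if (linear) {
    if (I_amu[3] < 1e-10) {
      rxnkin_stop("rxnkin_geometry_error",
                  "degenerate (coincident) coordinates for a polyatomic")
    }
    q <- T / (sigma * theta[3])                    # largest I <-> smallest theta
    pc$R_cal * (log(q) + 1)
  } else {
    if (any(I_amu < 1e-10)) {
      rxnkin_stop("rxnkin_geometry_error",
                  "degenerate coordinates: vanishing principal moment for ",
                  "a nonlinear rotor; check coordinates or the linear flag")
    }
    q <- sqrt(pi) / sigma * sqrt(T^3 / prod(theta))
    pc$R_cal * (log(q) + 1.5)
  }
}

# free-rotor entropy of one mode (cal/mol/K), Grimme-style, B_av = 1e-44 kg m^2
free_rotor_entropy_mode <- function(nu, T) {
  pc <- physical_constants
  B_av <- 1e-44
  mu <- pc$h / (8 * pi^2 * pc$c * nu)      # kg m^2
  mu_eff <- mu * B_av / (mu + B_av)
  q <- sqrt(8 * pi^3 * mu_eff * pc$kB * T / pc$h^2)
  pc$R_cal * (0.5 + log(q))
}

harmonic_mode_sv <- function(nu, T) {
  pc <- physical_constants
  x <- pc$h * pc$c * nu / (pc$kB * T)
  pc$R_cal * (x / expm1(x) - log1p(-exp(-x)))
}

#' Vibrational thermal energy and entropy
#'
#' Per real mode with `x = h*c*nu/(kB*T)`: thermal energy (ZPE excluded)
#' `E = R*T*x/(exp(x)-1)` and entropy
#' `S = R*(x/(exp(x)-1) - ln(1-exp(-x)))`, summed over modes. Imaginary
#' modes (negative wavenumbers) are excluded. Low-frequency treatments
#' affect the entropy only: `"floor"` replaces wavenumbers below `nu0` by
#' `nu0`; `"qrrho"` interpolates each mode between its harmonic and
#' free-rotor entropy with weight `w = 1/(1+(nu0/nu)^4)`.
#'
#' @param frequencies wavenumbers in cm^-1.
#' @param T temperature in K.
#' @param treatment `"none"`, `"floor"` or `"qrrho"`.
#' @param nu0 threshold wavenumber for the treatments.
#' @param scale frequency scale factor.
#' @return list with `e_vib` (kcal/mol) and `s_vib` (cal mol^-1 K^-1).
#' @export
vibrational_thermo <- function(frequencies, T = 298.15,
                               treatment = c("none", "floor", "qrrho"),
                               nu0 = 100, scale = 1) {
  treatment <- match.arg(treatment)
  if (T <= 0) rxnkin_stop("rxnkin_domain_error", "T must be > 0")
  pc <- physical_constants
  nu <- frequencies[frequencies > 0] * scale
  if (!length(nu)) return(list(e_vib = 0, s_vib = 0))
  x <- pc$h * pc$c * nu / (pc$kB * T)
  e_vib <- sum(pc$R * T * x / expm1(x)) / pc$cal_to_J / 1000  # kcal/mol

  s_vib <- switch(
    treatment,
    none = sum(harmonic_mode_sv(nu, T)),
    floor = sum(harmonic_mode_sv(pmax(nu, nu0), T)),
    qrrho = {
      w <- 1 / (1 + (nu0 / nu)^4)
      sum(w * harmonic_mode_sv(nu, T) +
            (1 - w) * vapply(nu, free_rotor_entropy_mode, 0, T = T))
    })
  list(e_vib = e_vib, s_vib = s_vib)
}

#' Electronic entropy
#'
#' `S_elec = R * ln(multiplicity)`, spin degeneracy only.
#'
#' @param multiplicity spin multiplicity, integer >= 1.
#' @return entropy in cal mol^-1 K^-1.
#' @export
electronic_entropy <- function(multiplicity) {
  if (multiplicity < 1) {
    rxnkin_stop("rxnkin_domain_error", "multiplicity must be >= 1")
  }
  physical_constants$R_cal * log(multiplicity)
}

#' Ideal-gas RRHO thermochemistry of one species
#'
#' Assembles enthalpy and Gibbs free energy from an electronic energy,
#' harmonic frequencies and a geometry:
#' `H = E_elec + ZPE + E_trans + E_rot + E_vib + R*T` (the last term is the
#' ideal-gas pV work), `G = H - T*S_total` with
#' `S_total = S_trans + S_rot + S_vib + S_elec`.
#'
#' A transition state (exactly one imaginary mode) is allowed; its imaginary
#' mode is excluded from all vibrational sums. Two or more imaginary modes
#' raise a validation error unless `validate = FALSE`.
#'
#' @param record a [qc_record()] (geometry required unless the species is
#'   treated as an atom via a 1-atom geometry).
#' @param conditions a [thermo_conditions()].
#' @param symmetry_number rotational symmetry number.
#' @param linear logical or NA (infer from geometry).
#' @param validate if TRUE, reject records with >= 2 imaginary modes.
#' @return an object of class `rxnkin_thermo` with components `zpe`,
#'   `e_thermal_trans`, `e_thermal_rot`, `e_thermal_vib` (kcal/mol),
#'   `s_trans`, `s_rot`, `s_vib`, `s_elec`, `entropy_total`
#'   (cal mol^-1 K^-1), `enthalpy`, `gibbs` (kcal/mol, including E_elec),
#'   and `T`.
#' @export
thermochemistry <- function(record, conditions = thermo_conditions(),
                            symmetry_number = 1, linear = NA,
                            validate = TRUE) {
  stopifnot(inherits(record, "rxnkin_qc_record"))
  if (is.null(record$geometry)) {
    rxnkin_stop("rxnkin_state_error",
                "thermochemistry needs a geometry (for mass and rotation)")
  }
  n_imag <- sum(record$frequencies < 0)
  if (validate && n_imag >= 2) {
    rxnkin_stop("rxnkin_validation_error", n_imag,
                " imaginary modes; a minimum has 0 and a transition state 1")
  }
  pc <- physical_constants
  T <- conditions$T
  RT_kcal <- pc$R * T / pc$cal_to_J / 1000
  geom <- record$geometry
  n_atoms <- length(geom$elements)
  mono <- n_atoms == 1
  if (is.na(linear)) linear <- if (mono) FALSE else is_linear_geometry(geom)

  zpe <- zero_point_energy(record$frequencies, conditions$frequency_scale)
  vib <- vibrational_thermo(record$frequencies, T,
                            treatment = conditions$low_freq_treatment,
                            nu0 = conditions$nu0,
                            scale = conditions$frequency_scale)
  mass <- sum(atomic_mass(geom$elements))
  s_trans <- translational_entropy(mass, T, effective_pressure(conditions))
  s_rot <- if (mono) 0 else
    rotational_entropy(geom, symmetry_number, T, linear)
  s_elec <- electronic_entropy(record$multiplicity)

  e_trans <- 1.5 * RT_kcal
  e_rot <- if (mono) 0 else if (linear) RT_kcal else 1.5 * RT_kcal
  e_elec_kcal <- record$electronic_energy * pc$hartree_to_kcal

  entropy_total <- s_trans + s_rot + vib$s_vib + s_elec
  enthalpy <- e_elec_kcal + zpe + e_trans + e_rot + vib$e_vib + RT_kcal
  gibbs <- enthalpy - T * entropy_total / 1000

  structure(list(
    zpe = zpe,
    e_thermal_trans = e_trans, e_thermal_rot = e_rot,
    e_thermal_vib = vib$e_vib,
    s_trans = s_trans, s_rot = s_rot, s_vib = vib$s_vib, s_elec = s_elec,
    entropy_total = entropy_total,
    enthalpy = enthalpy, gibbs = gibbs,
    electronic_energy = record$electronic_energy,
    n_imaginary = n_imag, T = T
  ), class = "rxnkin_thermo")
}

#' @export
print.rxnkin_thermo <- function(x, ...) {
  cat(sprintf("<thermochemistry at %.2f K>\n", x$T))
  cat(sprintf("  ZPE        %12.4f kcal/mol\n", x$zpe))
  cat(sprintf("  S(total)   %12.4f cal/mol/K  (trans %.3f | rot %.3f | vib %.3f | elec %.3f)\n",
              x$entropy_total, x$s_trans, x$s_rot, x$s_vib, x$s_elec))
  cat(sprintf("  H          %12.4f kcal/mol\n", x$enthalpy))
  cat(sprintf("  G          %12.4f kcal/mol\n", x$gibbs))
  invisible(x)
}
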