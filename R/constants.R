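#' Physical constants used throughout the package
#'
#' CODATA-2018 values. `kB`, `h` and `NA` are exact by the 2019 SI
#' redefinition; `amu` is the recommended value. The Hartree-to-kcal/mol
#' conversion is pinned so that relative energies are reproducible to the
#' last printed digit.
#'
#' @format A list with components:
#' \describe{
#'   \item{kB}{Boltzmann constant, J K^-1}
#'   \item{h}{Planck constant, J s}
#'   \item{c}{speed of light, cm s^-1 (wavenumber convention)}
#'   \item{NA}{Avogadro constant, mol^-1}
#'   \item{R}{molar gas constant kB*NA, J mol^-1 K^-1}
#'   \item{R_cal}{gas constant in cal mol^-1 K^-1}
#'   \item{amu}{atomic mass unit, kg}
#'   \item{hartree_to_kcal}{kcal mol^-1 per Hartree}
#'   \item{cal_to_J}{thermochemical calorie, J}
#' }
#' @export
physical_constants <- local({
  kB <- 1.380649e-23
  h  <- 6.62607015e-34
  NAv <- 6.02214076e23
  cal <- 4.184
  list(
    kB = kB,
    h = h,
    c = 2.99792458e10,
    `NA` = NAv,
    R = kB * NAv,
    R_cal = kB * NAv / cal,
    amu = 1.66053906660e-27,
    hartree_to_kcal = 627.5094740631,
    cal_to_J = cal
  )
})

# All IUPAC element symbols, used to validate parsed geometries.
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# Most-abundant-isotope masses (amu), pinned. Covers the elements a gas-phase
# mechanism study realistically touches; thermochemistry on anything else
# errors loudly rather than guessing.
ATOMIC_MASSES <- c(
  H = 1.00782503207, He = 4.00260325415,
  Li = 7.01600455, Be = 9.0121822, B = 11.0093054, C = 12.0,
  N = 14.0030740048, O = 15.99491461956, F = 18.99840322, Ne = 19.9924401754,
  Na = 22.9897692809, Mg = 23.9850417, Al = 26.98153863, Si = 27.9769265325,
  P = 30.97376163, S = 31.972071, Cl = 34.96885268, Ar = 39.9623831225,
  K = 38.96370668, Ca = 39.96259098, Sc = 44.9559119, Ti = 47.9479463,
  V = 50.9439595, Cr = 51.9405075, Mn = 54.9380451, Fe = 55.9349375,
  Co = 58.933195, Ni = 57.9353429, Cu = 62.9295975, Zn = 63.9291422,
  Ga = 68.9255736, Ge = 73.9211778, As = 74.9215965, Se = 79.9165213,
  Br = 78.9183371, Kr = 83.911507, Rb = 84.911789738, Sr = 87.9056121,
  Y = 88.9058483, Zr = 89.9047044, Nb = 92.9063781, Mo = 97.9054082,
  Ru = 101.9043493, Rh = 102.905504, Pd = 105.903486, Ag = 106.905097,
  Cd = 113.9033585, In = 114.903878, Sn = 119.9021947, Sb = 120.9038157,
  Te = 129.9062244, I = 126.904473, Xe = 131.9041535, Cs = 132.905451933,
  Ba = 137.9052472, W = 183.9509312, Re = 186.9557531, Os = 191.9614807,
  Ir = 192.9629264, Pt = 194.9647911, Au = 196.9665687, Hg = 201.970643,
  Tl = 204.9744275, Pb = 207.9766521, Bi = 208.9803987
)

#' Look up atomic masses for element symbols
#'
#' Masses are most-abundant-isotope values in amu, from a pinned internal
#' table.
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomic_mass <- function(elements) {
  m <- ATOMIC_MASSES[elements]
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    stop("rxnkin_mass_error: no pinned atomic mass for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(m)
}

# shared error helper: classed conditions so callers can test error classes
rxnkin_stop <- function(class, ...) {
  stop(structure(
    class = c(class, "rxnkin_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
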