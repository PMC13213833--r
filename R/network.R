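#' Construct a species record
#'
#' The central node of a reaction network: a named species with a role
#' (`minimum`, `transition_state` or `reference`), an electronic energy in
#' Hartree, and optionally a geometry, frequencies and computed
#' thermochemistry.
#'
#' @param name species name.
#' @param electronic_energy Hartree.
#' @param role one of `"minimum"`, `"transition_state"`, `"reference"`.
#' @param geometry a [geometry()] or NULL.
#' @param frequencies wavenumbers in cm^-1.
#' @param multiplicity spin multiplicity.
#' @param symmetry_number rotational symmetry number.
#' @param linear logical or NA.
#' @param composition named integer vector (element -> count); derived from
#'   the geometry when one is present.
#' @param thermo a `rxnkin_thermo` or NULL.
#' @param validate if TRUE, check the transition-state one-imaginary-mode
#'   signature.
#' @return an object of class `rxnkin_species`.
#' @export
species_record <- function(name, electronic_energy, role = "minimum",
                           geometry = NULL, frequencies = numeric(0),
                           multiplicity = 1L, symmetry_number = 1L,
                           linear = NA, composition = NULL, thermo = NULL,
                           validate = TRUE) {
  if (!role %in% MECHANISM_ROLES) {
    rxnkin_stop("rxnkin_schema_error", "unknown role ", dQuote(role))
  }
  if (!is.null(geometry)) {
    geo_comp <- composition_of(geometry)
    if (!is.null(composition) && !same_composition(composition, geo_comp)) {
      rxnkin_stop("rxnkin_composition_error",
                  "declared composition disagrees with geometry for ",
                  dQuote(name))
    }
    composition <- geo_comp
  }
  if (is.null(composition)) composition <- integer(0)
  n_imag <- sum(frequencies < 0)
  if (validate && role == "transition_state" && length(frequencies) &&
      n_imag != 1) {
    rxnkin_stop("rxnkin_validation_error", "transition state ", dQuote(name),
                " has ", n_imag, " imaginary modes (expected exactly 1)")
  }
  structure(list(name = name, role = role,
                 electronic_energy = as.numeric(electronic_energy),
                 geometry = geometry, frequencies = as.numeric(frequencies),
                 multiplicity = as.integer(multiplicity),
                 symmetry_number = as.integer(symmetry_number),
                 linear = linear, composition = composition,
                 thermo = thermo),
            class = "rxnkin_species")
}

#' @export
print.rxnkin_species <- function(x, ...) {
  cat(sprintf("<species %s> role = %s, E = %.8f Ha",
              dQuote(x$name), x$role, x$electronic_energy))
  if (length(x$composition)) {
    cat(" |", paste0(names(x$composition), x$composition, collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' Element composition of a geometry
#'
#' Exact integer counts per element symbol, order-independent (sorted by
#' symbol).
#'
#' @param geom a [geometry()].
#' @return named integer vector.
#' @export
composition <- function(geom) {
  UseMethod("composition")
}

#' @export
composition.rxnkin_geometry <- function(geom) composition_of(geom)

#' @export
composition.rxnkin_species <- function(geom) geom$composition

composition_of <- function(geom) {
  if (!length(geom$elements)) return(integer(0))
  tab <- table(geom$elements)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

same_composition <- function(a, b, tol = 1e-9) {
  els <- sort(union(names(a), names(b)))
  av <- ifelse(els %in% names(a), a[els], 0)
  bv <- ifelse(els %in% names(b), b[els], 0)
  av[is.na(av)] <- 0; bv[is.na(bv)] <- 0
  all(abs(av - bv) <= tol)
}

# element-wise weighted sum of compositions
sum_compositions <- function(comps, coeffs = rep(1, length(comps))) {
  els <- sort(unique(unlist(lapply(comps, names))))
  if (!length(els)) return(numeric(0))
  out <- stats::setNames(numeric(length(els)), els)
  for (i in seq_along(comps)) {
    ci <- comps[[i]]
    if (length(ci)) out[names(ci)] <- out[names(ci)] + coeffs[i] * ci
  }
  out
}

composition_imbalance_message <- function(target, got) {
  els <- sort(union(names(target), names(got)))
  tv <- stats::setNames(numeric(length(els)), els)
  gv <- tv
  if (length(target)) tv[names(target)] <- target
  if (length(got)) gv[names(got)] <- got
  d <- gv - tv
  bad <- els[abs(d) > 1e-9]
  paste0(bad, ": ", sprintf("%+g", d[bad]), collapse = ", ")
}

#' Merge intermediates into a single pseudo-species
#'
#' Sums the electronic energies, compositions and (when present on every
#' part) thermochemical quantities of several species, producing a merged
#' intermediate usable as a common reactant or product state. The part names
#' are retained as provenance.
#'
#' @param parts list of [species_record()]s, at least one.
#' @param name name of the merged species.
#' @return a [species_record()] with role `"minimum"`.
#' @export
merge_intermediates <- function(parts, name) {
  if (!length(parts)) {
    rxnkin_stop("rxnkin_domain_error", "merge_intermediates: empty part list")
  }
  stopifnot(all(vapply(parts, inherits, TRUE, "rxnkin_species")))
  e <- sum(vapply(parts, function(p) p$electronic_energy, 0))
  comp <- sum_compositions(lapply(parts, `[[`, "composition"))
  comp_int <- as.integer(round(comp)); names(comp_int) <- names(comp)
  thermo <- NULL
  if (all(vapply(parts, function(p) !is.null(p$thermo), TRUE))) {
    Ts <- vapply(parts, function(p) p$thermo$T, 0)
    if (max(Ts) - min(Ts) > 1e-9) {
      rxnkin_stop("rxnkin_state_error",
                  "cannot merge thermochemistry computed at different T")
    }
    add <- function(field) sum(vapply(parts, function(p) p$thermo[[field]], 0))
    thermo <- structure(list(
      zpe = add("zpe"),
      e_thermal_trans = add("e_thermal_trans"),
      e_thermal_rot = add("e_thermal_rot"),
      e_thermal_vib = add("e_thermal_vib"),
      s_trans = add("s_trans"), s_rot = add("s_rot"),
      s_vib = add("s_vib"), s_elec = add("s_elec"),
      entropy_total = add("entropy_total"),
      enthalpy = add("enthalpy"), gibbs = add("gibbs"),
      electronic_energy = e, n_imaginary = 0L, T = Ts[1]
    ), class = "rxnkin_thermo")
  }
  out <- species_record(name, e, role = "minimum", composition = comp_int,
                        thermo = thermo, validate = FALSE)
  attr(out, "merged_from") <- vapply(parts, function(p) p$name, "")
  out
}

# normalize a reference set: list of list(species=<rxnkin_species>, coeff=)
as_ref_list <- function(refs) {
  if (inherits(refs, "rxnkin_species")) {
    return(list(list(species = refs, coeff = 1)))
  }
  lapply(refs, function(r) {
    if (inherits(r, "rxnkin_species")) list(species = r, coeff = 1) else r
  })
}

species_value <- function(sp, property) {
  switch(property,
         electronic = sp$electronic_energy,
         gibbs = {
           if (is.null(sp$thermo)) {
             rxnkin_stop("rxnkin_state_error", "species ", dQuote(sp$name),
                         " has no thermochemistry; run thermochemistry() first")
           }
           sp$thermo$gibbs
         },
         enthalpy = {
           if (is.null(sp$thermo)) {
             rxnkin_stop("rxnkin_state_error", "species ", dQuote(sp$name),
                         " has no thermochemistry; run thermochemistry() first")
           }
           sp$thermo$enthalpy
         },
         rxnkin_stop("rxnkin_domain_error", "unknown property ",
                     dQuote(property)))
}

#' Relative energy of a species against its reference set
#'
#' `E_rel = value(species) - sum_j coeff_j * value(ref_j)`, converted to
#' kcal/mol for electronic energies (Hartree in, kcal/mol out); Gibbs and
#' enthalpy values are already in kcal/mol. The reference combination must
#' balance the species composition element-wise, otherwise a composition
#' error listing the imbalance is raised.
#'
#' @param species a [species_record()].
#' @param refs a reference set: a list of `list(species=, coeff=)` pairs (a
#'   bare [species_record()] means coefficient 1).
#' @param property `"electronic"`, `"gibbs"` or `"enthalpy"`.
#' @return relative energy in kcal/mol.
#' @export
relative_energy <- function(species, refs,
                            property = c("electronic", "gibbs", "enthalpy")) {
  property <- match.arg(property)
  refs <- as_ref_list(refs)
  coeffs <- vapply(refs, function(r) r$coeff, 0)
  ref_comp <- sum_compositions(lapply(refs, function(r) r$species$composition),
                               coeffs)
  if (!same_composition(species$composition, ref_comp)) {
    rxnkin_stop("rxnkin_composition_error",
                "reference combination does not balance ",
                dQuote(species$name), "; imbalance (refs - species): ",
                composition_imbalance_message(species$composition, ref_comp))
  }
  ref_val <- sum(coeffs * vapply(refs, function(r)
    species_value(r$species, property), 0))
  d <- species_value(species, property) - ref_val
  if (property == "electronic") d * physical_constants$hartree_to_kcal else d
}

#' Activation energy of a transition state relative to a preceding state
#'
#' Difference of the reference-based relative energies,
#' `Ea = E_rel(ts) - E_rel(from_state)`. The two states must share a
#' composition (so one reference set serves both) or carry their own
#' balancing reference sets.
#'
#' @param ts transition-state [species_record()].
#' @param from_state the state the barrier is measured from.
#' @param refs reference set for `ts` (and for `from_state` unless
#'   `refs_from` is given).
#' @param refs_from optional separate reference set for `from_state`.
#' @param property `"electronic"`, `"gibbs"` or `"enthalpy"`.
#' @return activation energy in kcal/mol.
#' @export
activation_energy <- function(ts, from_state, refs, refs_from = refs,
                              property = c("electronic", "gibbs",
                                           "enthalpy")) {
  property <- match.arg(property)
  relative_energy(ts, refs, property) -
    relative_energy(from_state, refs_from, property)
}

#' Reaction energy between two states
#'
#' `dE = E_rel(b) - E_rel(a)` on a common reference footing.
#'
#' @param a,b [species_record()]s (initial and final state).
#' @param refs reference set for both (or for `a` if `refs_b` given).
#' @param refs_b optional separate reference set for `b`.
#' @param property `"electronic"`, `"gibbs"` or `"enthalpy"`.
#' @return reaction energy in kcal/mol.
#' @export
reaction_energy <- function(a, b, refs, refs_b = refs,
                            property = c("electronic", "gibbs", "enthalpy")) {
  property <- match.arg(property)
  relative_energy(b, refs_b, property) - relative_energy(a, refs, property)
}

#' Build an energy profile along a reaction coordinate
#'
#' Computes reference-based relative energies for an ordered list of states.
#' The reference defines the zero, so the first state need not sit at 0.
#'
#' @param states ordered list of [species_record()]s.
#' @param refs common reference set, or a named list of reference sets keyed
#'   by species name.
#' @param property `"electronic"`, `"gibbs"` or `"enthalpy"`.
#' @param T temperature label (K) attached to the profile.
#' @return a data.frame of class `rxnkin_profile` with columns `label`,
#'   `value` (kcal/mol) and `role`.
#' @export
build_profile <- function(states, refs,
                          property = c("electronic", "gibbs", "enthalpy"),
                          T = NA_real_) {
  property <- match.arg(property)
  labels <- vapply(states, function(s) s$name, "")
  if (anyDuplicated(labels)) {
    rxnkin_stop("rxnkin_schema_error", "duplicate state labels in profile")
  }
  per_state_refs <- !is.null(names(refs)) &&
    all(labels %in% names(refs))
  vals <- vapply(seq_along(states), function(i) {
    r <- if (per_state_refs) refs[[labels[i]]] else refs
    relative_energy(states[[i]], r, property)
  }, 0)
  out <- data.frame(label = labels, value = vals,
                    role = vapply(states, function(s) s$role, ""),
                    stringsAsFactors = FALSE)
  class(out) <- c("rxnkin_profile", "data.frame")
  attr(out, "property") <- property
  attr(out, "T") <- T
  out
}

#' @export
print.rxnkin_profile <- function(x, ...) {
  cat("<energy profile> property = ", attr(x, "property"),
      if (!is.na(attr(x, "T"))) paste0(", T = ", attr(x, "T"), " K"),
      "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Solve for reference coefficients by composition balance
#'
#' Finds coefficients `c_j >= 0` with
#' `sum_j c_j * composition(ref_j) == composition(species)` when the linear
#' system is uniquely determined; errors if it is rank-deficient or
#' inconsistent.
#'
#' @param species a [species_record()].
#' @param refs list of candidate reference [species_record()]s.
#' @return numeric coefficient vector named by reference species.
#' @export
solve_reference_coefficients <- function(species, refs) {
  els <- sort(unique(c(names(species$composition),
                       unlist(lapply(refs, function(r) names(r$composition))))))
  A <- vapply(refs, function(r) {
    v <- stats::setNames(numeric(length(els)), els)
    if (length(r$composition)) v[names(r$composition)] <- r$composition
    v
  }, numeric(length(els)))
  A <- matrix(A, nrow = length(els))
  b <- stats::setNames(numeric(length(els)), els)
  if (length(species$composition)) {
    b[names(species$composition)] <- species$composition
  }
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    rxnkin_stop("rxnkin_composition_error",
                "reference set is not uniquely determined (rank deficient)")
  }
  coeff <- qr.solve(qr_A, b)
  if (max(abs(A %*% coeff - b)) > 1e-9 || any(coeff < -1e-9)) {
    rxnkin_stop("rxnkin_composition_error",
                "no non-negative reference combination balances ",
                dQuote(species$name))
  }
  stats::setNames(as.numeric(coeff),
                  vapply(refs, function(r) r$name, ""))
}
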