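#' Build a species record from a mechanism entry
#'
#' Parses the inline XYZ geometry (when present) and carries energies,
#' frequencies and rotor metadata over to a [species_record()].
#'
#' @param entry a [mechanism_entry()].
#' @return a [species_record()].
#' @export
species_from_entry <- function(entry) {
  geom <- if (is.null(entry$geometry_xyz)) NULL else
    parse_xyz_text(entry$geometry_xyz, src = entry$name)
  species_record(
    name = entry$name, role = entry$role,
    electronic_energy = if (is.null(entry$energy_hartree)) NA_real_ else
      entry$energy_hartree,
    geometry = geom,
    frequencies = if (is.null(entry$frequencies_cm1)) numeric(0) else
      entry$frequencies_cm1,
    multiplicity = entry$multiplicity,
    symmetry_number = entry$symmetry_number,
    linear = entry$linear,
    validate = FALSE
  )
}

#' All species of a mechanism, as records
#'
#' @param mech a [mechanism()].
#' @param conditions optional [thermo_conditions()]; when given,
#'   thermochemistry is computed for every entry carrying a geometry and
#'   frequencies.
#' @return named list of [species_record()]s (all networks pooled).
#' @export
mechanism_species <- function(mech, conditions = NULL) {
  sp <- list()
  for (nw in mech$networks) {
    for (e in nw$entries) {
      s <- species_from_entry(e)
      if (!is.null(conditions) && !is.null(s$geometry) &&
          length(s$frequencies)) {
        rec <- qc_record(s$electronic_energy, s$geometry, s$frequencies,
                         s$multiplicity)
        s$thermo <- thermochemistry(rec, conditions,
                                    symmetry_number = s$symmetry_number,
                                    linear = s$linear, validate = FALSE)
      }
      sp[[s$name]] <- s
    }
  }
  sp
}

# resolve an entry's reference assignment into a list(species=, coeff=) set
resolve_references <- function(entry, species_pool) {
  lapply(entry$references, function(r)
    list(species = species_pool[[r$name]], coeff = r$coeff))
}

#' Thermochemistry table for a whole mechanism
#'
#' One row per species per temperature; the canonical table behind the CSV
#' export. Species without frequencies or geometry get electronic energy
#' only (thermo columns NA).
#'
#' @param mech a [mechanism()].
#' @param temperatures temperatures in K; defaults to the mechanism setting.
#' @param standard_state standard state for the translational entropy.
#' @return data.frame with columns `network`, `species`, `role`,
#'   `temperature_K`, `electronic_energy_hartree`, `zpe_kcal_mol`,
#'   `enthalpy_kcal_mol`, `entropy_cal_mol_K`, `gibbs_kcal_mol`.
#' @export
mechanism_thermo_table <- function(mech,
                                   temperatures = mech$settings$temperature_K,
                                   standard_state = "gas_1atm") {
  rows <- list()
  for (T in temperatures) {
    cond <- thermo_conditions(T = T, P = mech$settings$pressure_Pa,
                              standard_state = standard_state)
    for (nw in mech$networks) {
      for (e in nw$entries) {
        s <- species_from_entry(e)
        th <- NULL
        if (!is.null(s$geometry) && length(s$frequencies) &&
            is.finite(s$electronic_energy)) {
          rec <- qc_record(s$electronic_energy, s$geometry, s$frequencies,
                           s$multiplicity)
          th <- thermochemistry(rec, cond,
                                symmetry_number = s$symmetry_number,
                                linear = s$linear, validate = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          network = nw$name, species = e$name, role = e$role,
          temperature_K = T,
          electronic_energy_hartree = s$electronic_energy,
          zpe_kcal_mol = if (is.null(th)) NA_real_ else th$zpe,
          enthalpy_kcal_mol = if (is.null(th)) NA_real_ else th$enthalpy,
          entropy_cal_mol_K = if (is.null(th)) NA_real_ else
            th$entropy_total,
          gibbs_kcal_mol = if (is.null(th)) NA_real_ else th$gibbs,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Reference-based relative energies for every referenced species
#'
#' @param mech a [mechanism()].
#' @param property `"electronic"`, `"gibbs"` or `"enthalpy"`.
#' @param conditions [thermo_conditions()] used when `property` needs
#'   thermochemistry.
#' @return data.frame `network`, `species`, `role`,
#'   `relative_energy_kcal_mol` (NA for species without references).
#' @export
mechanism_relative_energies <- function(mech, property = "electronic",
                                        conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- thermo_conditions(T = mech$settings$temperature_K,
                                    P = mech$settings$pressure_Pa)
  }
  pool <- mechanism_species(mech,
                            conditions = if (property == "electronic") NULL
                            else conditions)
  rows <- list()
  for (nw in mech$networks) {
    for (e in nw$entries) {
      rel <- NA_real_
      if (length(e$references)) {
        refs <- resolve_references(e, pool)
        rel <- relative_energy(pool[[e$name]], refs, property)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        network = nw$name, species = e$name, role = e$role,
        relative_energy_kcal_mol = rel, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Elementary-step rate table for a mechanism
#'
#' Within each network the entry order is the reaction coordinate: every
#' transition-state entry defines a step between its nearest preceding and
#' following non-TS states. Barriers are differences of reference-based
#' relative energies; rate constants come from [eyring_rate()].
#'
#' @param mech a [mechanism()].
#' @param temperatures temperatures in K.
#' @param property energy property used for barriers (`"gibbs"` needs
#'   frequencies + geometries on all states).
#' @param kappa transmission coefficient.
#' @param standard_state standard state passed to [eyring_rate()].
#' @return data.frame `network`, `step`, `ts`, `from`, `to`,
#'   `temperature_K`, `dg_forward_kcal_mol`, `dg_reverse_kcal_mol`, `k_f`,
#'   `k_r`.
#' @export
mechanism_step_table <- function(mech,
                                 temperatures = mech$settings$temperature_K,
                                 property = "gibbs", kappa = 1,
                                 standard_state = "solution_1M") {
  rows <- list()
  for (T in temperatures) {
    cond <- thermo_conditions(T = T, P = mech$settings$pressure_Pa)
    pool <- mechanism_species(mech,
                              conditions = if (property == "electronic")
                                NULL else cond)
    entry_pool <- list()
    for (nw in mech$networks) for (e in nw$entries) entry_pool[[e$name]] <- e
    rel <- function(name) {
      e <- entry_pool[[name]]
      if (!length(e$references)) {
        rxnkin_stop("rxnkin_reference_error", "species ", dQuote(name),
                    " has no reference assignment; cannot place it on a ",
                    "common energy scale")
      }
      relative_energy(pool[[name]], resolve_references(e, pool), property)
    }
    for (nw in mech$networks) {
      roles <- vapply(nw$entries, function(e) e$role, "")
      names_nw <- vapply(nw$entries, function(e) e$name, "")
      ts_idx <- which(roles == "transition_state")
      for (s in seq_along(ts_idx)) {
        i <- ts_idx[s]
        before <- which(roles[seq_len(i - 1)] != "transition_state")
        after <- which(roles != "transition_state" &
                         seq_along(roles) > i)
        if (!length(before) || !length(after)) next
        from <- names_nw[max(before)]
        to <- names_nw[min(after)]
        dgf <- rel(names_nw[i]) - rel(from)
        dgr <- rel(names_nw[i]) - rel(to)
        rows[[length(rows) + 1L]] <- data.frame(
          network = nw$name, step = s, ts = names_nw[i], from = from,
          to = to, temperature_K = T,
          dg_forward_kcal_mol = dgf, dg_reverse_kcal_mol = dgr,
          k_f = eyring_rate(dgf, T, kappa,
                            standard_state = standard_state)$value,
          k_r = eyring_rate(dgr, T, kappa,
                            standard_state = standard_state)$value,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
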