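#' Construct a molecular geometry
#'
#' A geometry is a set of atoms with Cartesian coordinates in Angstrom.
#' Element symbols are validated against the periodic table.
#'
#' @param elements character vector of element symbols.
#' @param coordinates numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom), or a vector of length 3*n.
#' @param comment free-text comment (XYZ line 2).
#' @return an object of class `rxnkin_geometry`.
#' @export
geometry <- function(elements, coordinates, comment = "") {
  elements <- as.character(elements)
  if (is.null(dim(coordinates))) {
    coordinates <- matrix(as.numeric(coordinates), ncol = 3, byrow = TRUE)
  }
  coordinates <- unname(as.matrix(coordinates))
  if (nrow(coordinates) != length(elements)) {
    rxnkin_stop("rxnkin_parse_error",
                "geometry: ", length(elements), " elements but ",
                nrow(coordinates), " coordinate rows")
  }
  if (length(coordinates) && !all(is.finite(coordinates))) {
    rxnkin_stop("rxnkin_parse_error", "geometry: non-finite coordinates")
  }
  bad <- setdiff(unique(elements), ELEMENT_SYMBOLS)
  if (length(bad)) {
    rxnkin_stop("rxnkin_unknown_element_error",
                "unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  structure(list(elements = elements, coordinates = coordinates,
                 comment = as.character(comment)[1]),
            class = "rxnkin_geometry")
}

#' @export
print.rxnkin_geometry <- function(x, ...) {
  cat("<geometry> ", length(x$elements), " atoms",
      if (nzchar(x$comment)) paste0(" | ", x$comment), "\n", sep = "")
  comp <- composition(x)
  if (length(comp)) {
    cat("  composition:",
        paste0(names(comp), comp, collapse = " "), "\n")
  }
  invisible(x)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: line 1 atom count, line 2 comment, then `element x y z`
#' rows.
#'
#' @param path file path.
#' @return a [geometry()] object.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) {
    rxnkin_stop("rxnkin_io_error", "file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  parse_xyz_text(lines, src = path)
}

# shared by read_xyz and the geometry_xyz field of mechanism JSON
parse_xyz_text <- function(lines, src = "<text>") {
  if (is.character(lines) && length(lines) == 1L && grepl("\n", lines)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  if (!length(lines)) {
    rxnkin_stop("rxnkin_parse_error", "empty XYZ input: ", src)
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0 || trimws(lines[1]) != as.character(n)) {
    rxnkin_stop("rxnkin_parse_error",
                "malformed XYZ atom-count line in ", src, ": ",
                dQuote(lines[1]))
  }
  comment <- if (length(lines) >= 2) lines[2] else ""
  body <- lines[-(1:2)]
  body <- body[seq_len(min(length(body), n))]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    rxnkin_stop("rxnkin_truncated_file_error",
                src, ": declared ", n, " atoms, found ", length(body),
                " coordinate lines")
  }
  fields <- strsplit(trimws(body), "\\s+")
  ok <- vapply(fields, length, 1L) >= 4L
  if (!all(ok)) {
    rxnkin_stop("rxnkin_parse_error", src, ": malformed coordinate line: ",
                dQuote(body[!ok][1]))
  }
  elements <- vapply(fields, `[[`, "", 1L)
  coords <- t(vapply(fields,
                     function(f) suppressWarnings(as.numeric(f[2:4])),
                     numeric(3)))
  if (n == 0L) coords <- matrix(numeric(0), 0, 3)
  if (length(coords) && anyNA(coords)) {
    rxnkin_stop("rxnkin_parse_error", src, ": non-numeric coordinates")
  }
  geometry(elements, coords, comment)
}

#' Write an XYZ geometry file
#'
#' Coordinates are written with 10 decimal places so that read/write round
#' trips are exact at test precision.
#'
#' @param geom a [geometry()] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_xyz <- function(geom, path) {
  stopifnot(inherits(geom, "rxnkin_geometry"))
  writeLines(format_xyz_text(geom), path)
  invisible(path)
}

format_xyz_text <- function(geom) {
  n <- length(geom$elements)
  rows <- if (n) {
    sprintf("%-3s %16.10f %16.10f %16.10f", geom$elements,
            geom$coordinates[, 1], geom$coordinates[, 2],
            geom$coordinates[, 3])
  } else character(0)
  c(as.character(n), geom$comment, rows)
}

#' Construct a raw quantum-chemistry record
#'
#' Holds what a frequency calculation provides: final electronic energy
#' (Hartree), geometry, harmonic wavenumbers (imaginary modes negative) and
#' spin multiplicity.
#'
#' @param electronic_energy final electronic energy in Hartree.
#' @param geometry a [geometry()] or NULL.
#' @param frequencies numeric vector of wavenumbers in cm^-1; may be empty.
#' @param multiplicity spin multiplicity, integer >= 1.
#' @param source_path provenance string.
#' @return an object of class `rxnkin_qc_record`.
#' @export
qc_record <- function(electronic_energy, geometry = NULL,
                      frequencies = numeric(0), multiplicity = 1L,
                      source_path = NA_character_) {
  if (!is.finite(electronic_energy)) {
    rxnkin_stop("rxnkin_domain_error", "electronic energy must be finite")
  }
  if (multiplicity < 1) {
    rxnkin_stop("rxnkin_domain_error", "multiplicity must be >= 1")
  }
  structure(list(electronic_energy = as.numeric(electronic_energy),
                 geometry = geometry,
                 frequencies = as.numeric(frequencies),
                 multiplicity = as.integer(multiplicity),
                 source_path = source_path),
            class = "rxnkin_qc_record")
}

#' @export
print.rxnkin_qc_record <- function(x, ...) {
  n_im <- sum(x$frequencies < 0)
  cat(sprintf("<qc record> E_elec = %.9f Ha | %d frequencies (%d imaginary) | mult %d\n",
              x$electronic_energy, length(x$frequencies), n_im,
              x$multiplicity))
  invisible(x)
}

#' Parse an ORCA-style frequency output
#'
#' Supports the dialect emitted by [make_orca_like_text()]: a
#' `FINAL SINGLE POINT ENERGY` line (the last occurrence wins, as in an
#' optimization trace), an optional `VIBRATIONAL FREQUENCIES` block with
#' `index: value cm**-1` lines, an optional
#' `CARTESIAN COORDINATES (ANGSTROEM)` block, and an optional
#' `Multiplicity  Mult  ....  n` line. Real ORCA outputs whose sections match
#' this grammar also parse. Exact-zero frequencies (translational/rotational
#' placeholders) are dropped; imaginary modes are kept as negative
#' wavenumbers.
#'
#' @param text character vector of lines, a single string with newlines, or a
#'   file path.
#' @return a [qc_record()].
#' @export
parse_orca_like <- function(text) {
  src <- "<text>"
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    src <- text
    text <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }

  e_lines <- grep("FINAL SINGLE POINT ENERGY", text, fixed = TRUE)
  if (!length(e_lines)) {
    rxnkin_stop("rxnkin_missing_energy_error",
                src, ": no FINAL SINGLE POINT ENERGY line")
  }
  e_txt <- sub(".*FINAL SINGLE POINT ENERGY\\s+", "", text[max(e_lines)])
  energy <- suppressWarnings(as.numeric(trimws(e_txt)))
  if (is.na(energy)) {
    rxnkin_stop("rxnkin_parse_error", src, ": unreadable energy value ",
                dQuote(trimws(e_txt)))
  }

  mult <- 1L
  m_line <- grep("^\\s*Multiplicity\\s+Mult", text)
  if (length(m_line)) {
    m_txt <- sub(".*\\.\\.\\.\\.\\s*", "", text[m_line[1]])
    mult <- suppressWarnings(as.integer(trimws(m_txt)))
    if (is.na(mult)) {
      rxnkin_stop("rxnkin_parse_error", src, ": unreadable multiplicity")
    }
  }

  freqs <- numeric(0)
  f_head <- grep("VIBRATIONAL FREQUENCIES", text, fixed = TRUE)
  if (length(f_head)) {
    block <- text[seq(f_head[1] + 1L, length(text))]
    is_line <- grepl("^\\s*\\d+:\\s", block)
    # the block ends at the first non-matching, non-blank, non-dashed line
    body_end <- which(!is_line & nzchar(trimws(block)) &
                        !grepl("^-+$", trimws(block)))
    keep <- if (length(body_end)) seq_len(body_end[1] - 1L) else
      seq_along(block)
    flines <- block[keep][is_line[keep]]
    if (length(flines)) {
      vals <- sub("^\\s*\\d+:\\s+(-?[0-9.]+)\\s+cm\\*\\*-1.*$", "\\1", flines)
      bad <- vals == flines
      if (any(bad)) {
        rxnkin_stop("rxnkin_parse_error", src,
                    ": malformed frequency line: ", dQuote(flines[bad][1]))
      }
      freqs <- as.numeric(vals)
      freqs <- freqs[freqs != 0]   # drop exact-zero placeholder modes
    }
  }

  geom <- NULL
  g_head <- grep("CARTESIAN COORDINATES (ANGSTROEM)", text, fixed = TRUE)
  if (length(g_head)) {
    block <- text[seq(g_head[1] + 1L, length(text))]
    start <- which(grepl("^\\s*[A-Z][a-z]?\\s+-?[0-9]", block))
    if (length(start)) {
      i <- start[1]
      rows <- character(0)
      while (i <= length(block) && grepl("^\\s*[A-Z][a-z]?\\s+-?[0-9]", block[i])) {
        rows <- c(rows, block[i]); i <- i + 1L
      }
      fields <- strsplit(trimws(rows), "\\s+")
      geom <- geometry(vapply(fields, `[[`, "", 1L),
                       t(vapply(fields,
                                function(f) as.numeric(f[2:4]), numeric(3))))
    }
  }

  qc_record(energy, geom, freqs, mult, source_path = src)
}

# ---- mechanism JSON -------------------------------------------------------

MECHANISM_ROLES <- c("minimum", "transition_state", "reference")

#' Construct a mechanism entry
#'
#' One species slot of a mechanism network: role, energies, frequencies,
#' optional inline XYZ geometry, and reference assignments (name +
#' stoichiometric coefficient pairs defining the zero of relative energy).
#'
#' @param name species name, unique within the mechanism.
#' @param role one of `"minimum"`, `"transition_state"`, `"reference"`.
#' @param energy_hartree electronic energy (Hartree) or NULL.
#' @param frequencies_cm1 wavenumbers or NULL.
#' @param geometry_xyz inline XYZ text or NULL.
#' @param multiplicity spin multiplicity.
#' @param symmetry_number rotational symmetry number.
#' @param linear logical, linear rotor flag.
#' @param source provenance string or NULL.
#' @param references list of `list(name=, coeff=)` pairs.
#' @return a list of class `rxnkin_mech_entry`.
#' @export
mechanism_entry <- function(name, role = "minimum", energy_hartree = NULL,
                            frequencies_cm1 = NULL, geometry_xyz = NULL,
                            multiplicity = 1L, symmetry_number = 1L,
                            linear = FALSE, source = NULL,
                            references = list()) {
  if (!role %in% MECHANISM_ROLES) {
    rxnkin_stop("rxnkin_schema_error", "unknown role ", dQuote(role),
                " for species ", dQuote(name),
                " (expected minimum | transition_state | reference)")
  }
  structure(list(name = name, role = role,
                 energy_hartree = energy_hartree,
                 frequencies_cm1 = frequencies_cm1,
                 geometry_xyz = geometry_xyz,
                 multiplicity = as.integer(multiplicity),
                 symmetry_number = as.integer(symmetry_number),
                 linear = isTRUE(linear),
                 source = source,
                 references = references),
            class = "rxnkin_mech_entry")
}

#' Construct a mechanism
#'
#' The data model of a mechanism file: named networks of species entries plus
#' global settings (temperature and pressure).
#'
#' @param networks list of `list(name=, entries=list of [mechanism_entry()])`.
#' @param temperature_K default temperature.
#' @param pressure_Pa default pressure.
#' @return an object of class `rxnkin_mechanism`.
#' @export
mechanism <- function(networks = list(), temperature_K = 298.15,
                      pressure_Pa = 101325) {
  m <- structure(list(version = 1L, networks = networks,
                      settings = list(temperature_K = temperature_K,
                                      pressure_Pa = pressure_Pa)),
                 class = "rxnkin_mechanism")
  validate_mechanism(m)
  m
}

validate_mechanism <- function(m) {
  all_names <- unlist(lapply(m$networks, function(nw)
    vapply(nw$entries, function(e) e$name, "")))
  if (anyDuplicated(all_names)) {
    rxnkin_stop("rxnkin_schema_error", "duplicate species name(s): ",
                paste(unique(all_names[duplicated(all_names)]),
                      collapse = ", "))
  }
  for (nw in m$networks) {
    for (e in nw$entries) {
      if (!e$role %in% MECHANISM_ROLES) {
        rxnkin_stop("rxnkin_schema_error", "unknown role ", dQuote(e$role),
                    " for species ", dQuote(e$name))
      }
      for (ref in e$references) {
        if (!ref$name %in% all_names) {
          rxnkin_stop("rxnkin_reference_error", "species ", dQuote(e$name),
                      " references undeclared species ", dQuote(ref$name))
        }
      }
    }
  }
  invisible(m)
}

#' @export
print.rxnkin_mechanism <- function(x, ...) {
  n_sp <- sum(vapply(x$networks, function(nw) length(nw$entries), 1L))
  cat("<mechanism> ", length(x$networks), " network(s), ", n_sp,
      " species | T = ", x$settings$temperature_K, " K, P = ",
      x$settings$pressure_Pa, " Pa\n", sep = "")
  for (nw in x$networks) {
    roles <- vapply(nw$entries, function(e) e$role, "")
    cat(sprintf("  %s: %d species (%d minima, %d TS, %d references)\n",
                nw$name, length(roles), sum(roles == "minimum"),
                sum(roles == "transition_state"), sum(roles == "reference")))
  }
  invisible(x)
}

#' Load a mechanism from JSON
#'
#' Schema: `{"version": 1, "networks": [{"name", "entries": [...]}],
#' "settings": {"temperature_K", "pressure_Pa"}}`; see [mechanism_entry()]
#' for entry fields. Unknown roles raise a schema error; references to
#' undeclared species raise a reference error.
#'
#' @param path JSON file path.
#' @return a [mechanism()].
#' @export
load_mechanism <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  networks <- lapply(raw$networks, function(nw) {
    entries <- lapply(nw$entries, function(e) {
      mechanism_entry(
        name = e$name,
        role = if (is.null(e$role)) "minimum" else e$role,
        energy_hartree = if (is.null(e$energy_hartree)) NULL else
          as.numeric(e$energy_hartree),
        frequencies_cm1 = if (is.null(e$frequencies_cm1)) NULL else
          as.numeric(unlist(e$frequencies_cm1)),
        geometry_xyz = e$geometry_xyz,
        multiplicity = if (is.null(e$multiplicity)) 1L else e$multiplicity,
        symmetry_number = if (is.null(e$symmetry_number)) 1L else
          e$symmetry_number,
        linear = isTRUE(e$linear),
        source = e$source,
        references = if (is.null(e$references)) list() else
          lapply(e$references, function(r)
            list(name = r$name, coeff = as.numeric(r$coeff)))
      )
    })
    list(name = nw$name, entries = entries)
  })
  st <- raw$settings
  mechanism(networks,
            temperature_K = if (is.null(st$temperature_K)) 298.15 else
              st$temperature_K,
            pressure_Pa = if (is.null(st$pressure_Pa)) 101325 else
              st$pressure_Pa)
}

#' Save a mechanism to JSON
#'
#' Inverse of [load_mechanism()]; `load_mechanism(save_mechanism(m))` is the
#' identity.
#'
#' @param mech a [mechanism()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
save_mechanism <- function(mech, path) {
  stopifnot(inherits(mech, "rxnkin_mechanism"))
  out <- list(
    version = 1L,
    networks = lapply(mech$networks, function(nw) list(
      name = nw$name,
      entries = lapply(nw$entries, function(e) {
        list(name = e$name, role = e$role,
             energy_hartree = e$energy_hartree,
             frequencies_cm1 = if (is.null(e$frequencies_cm1)) NULL else
               as.list(e$frequencies_cm1),
             geometry_xyz = e$geometry_xyz,
             multiplicity = e$multiplicity,
             symmetry_number = e$symmetry_number,
             linear = e$linear,
             source = e$source,
             references = lapply(e$references, function(r)
               list(name = r$name, coeff = r$coeff)))
      })
    )),
    settings = mech$settings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export a results table to CSV
#'
#' Writes one row per species per temperature with a fixed header taken from
#' the column names of `results`. UTF-8, `.` decimal separator, `,` field
#' separator, no locale sensitivity; `utils::read.csv()` reproduces the
#' numeric table at printed precision.
#'
#' @param results a data.frame, e.g. from [mechanism_thermo_table()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_results_csv <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.csv(results, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
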