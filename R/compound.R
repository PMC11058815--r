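# Element bookkeeping: nuclear charge, valence-electron convention and molar
# mass for the elements appearing in the built-in polymers. The valence
# convention (H:1, C:4, N:5, O:6) counts bonding electrons only.
element_table <- function() {
  data.frame(
    symbol = c("H", "C", "N", "O"),
    Z = c(1L, 6L, 7L, 8L),
    valence = c(1L, 4L, 5L, 6L),
    mass = c(1.008, 12.011, 14.007, 15.999),
    stringsAsFactors = FALSE
  )
}

# internal: look up a column of the element table for a composition's symbols
element_lookup <- function(symbols, column) {
  tab <- element_table()
  idx <- match(symbols, tab$symbol)
  if (anyNA(idx)) {
    stop("unknown element(s): ", paste(symbols[is.na(idx)], collapse = ", "))
  }
  tab[[column]][idx]
}

#' Total and valence electron counts of a monomer composition
#'
#' @param composition named integer vector of atoms per monomer, e.g.
#'   \code{c(C = 5, H = 8, O = 2)}. Elements must be among H, C, N, O.
#' @return A list with integer \code{total} (sum of nuclear charges) and
#'   \code{valence} (bonding electrons, H:1 C:4 N:5 O:6).
#' @examples
#' electron_counts(c(C = 2, H = 2))  # 14 total, 10 valence
#' @export
electron_counts <- function(composition) {
  composition <- validate_composition(composition)
  syms <- names(composition)
  list(
    total = as.integer(sum(composition * element_lookup(syms, "Z"))),
    valence = as.integer(sum(composition * element_lookup(syms, "valence")))
  )
}

# internal: composition validation shared by material() and friends
validate_composition <- function(composition) {
  if (is.null(names(composition)) || any(names(composition) == "")) {
    stop("composition must be a named vector (element symbol -> count)")
  }
  if (length(composition) == 0) stop("composition must be non-empty")
  counts <- as.numeric(composition)
  if (any(!is.finite(counts)) || any(counts <= 0) ||
      any(counts != round(counts))) {
    stop("composition counts must be positive integers")
  }
  stats::setNames(as.integer(counts), names(composition))
}

#' Monomer molar mass
#'
#' @param composition named atom counts per monomer.
#' @return Molar mass in g/mol.
#' @export
monomer_mass <- function(composition) {
  composition <- validate_composition(composition)
  sum(composition * element_lookup(names(composition), "mass"))
}

#' Material definition
#'
#' Bundles a polymer's (or any compound's) monomer composition, mass density
#' and Penn-relevant metadata. Electron counts are derived from the
#' composition and, when the reference counts are supplied, checked against
#' them.
#'
#' @param name material name.
#' @param composition named atoms-per-monomer vector.
#' @param density mass density in g/cm^3 (> 0).
#' @param unique_rs the single Wigner-Seitz radius (bohr) used when the
#'   material is approximated by one homogeneous electron gas; \code{NA} if
#'   not defined.
#' @param elf_range optional length-2 numeric, the energy range (eV) over
#'   which the material's measured ELF is tabulated.
#' @param formula_printed optional free-text formula as printed in the source
#'   reference (kept when it differs from \code{composition}).
#' @param total_electrons,valence_electrons optional reference counts; an
#'   error is raised if they disagree with the composition.
#' @return An object of class \code{material}.
#' @export
material <- function(name, composition, density, unique_rs = NA_real_,
                     elf_range = NULL, formula_printed = NULL,
                     total_electrons = NULL, valence_electrons = NULL) {
  composition <- validate_composition(composition)
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  cnt <- electron_counts(composition)
  if (!is.null(total_electrons) && total_electrons != cnt$total) {
    stop(sprintf("%s: composition gives %d total electrons, expected %d",
                 name, cnt$total, total_electrons))
  }
  if (!is.null(valence_electrons) && valence_electrons != cnt$valence) {
    stop(sprintf("%s: composition gives %d valence electrons, expected %d",
                 name, cnt$valence, valence_electrons))
  }
  structure(list(
    name = as.character(name)[1],
    composition = composition,
    density = density,
    total_electrons = cnt$total,
    valence_electrons = cnt$valence,
    unique_rs = unique_rs,
    elf_range = elf_range,
    formula_printed = formula_printed,
    molar_mass = monomer_mass(composition),
    atoms_per_monomer = as.integer(sum(composition))
  ), class = "material")
}

#' @export
print.material <- function(x, ...) {
  comp <- paste0(names(x$composition), x$composition, collapse = "")
  cat(sprintf("material %s (%s): rho = %.2f g/cm3, %d/%d electrons (total/valence), M = %.3f g/mol",
              x$name, comp, x$density, x$total_electrons, x$valence_electrons,
              x$molar_mass))
  if (is.finite(x$unique_rs)) cat(sprintf(", unique-FEG r_s = %.2f bohr", x$unique_rs))
  cat("\n")
  if (!is.null(x$formula_printed)) {
    cat(sprintf("  (source prints formula %s; registered composition matches the printed electron counts)\n",
                x$formula_printed))
  }
  invisible(x)
}

# internal: monomer number density in atomic units (bohr^-3)
monomer_number_density_au <- function(material) {
  stopifnot(inherits(material, "material"))
  n_cm3 <- material$density * pennstop_constants$avogadro / material$molar_mass
  n_cm3 * pennstop_constants$bohr_cm^3
}

# internal: atom number density in cm^-3
atom_number_density_cm3 <- function(material) {
  material$density * pennstop_constants$avogadro *
    material$atoms_per_monomer / material$molar_mass
}

#' Built-in polymer registry
#'
#' The six polymers commonly used in proton-therapy phantoms and accelerator
#' components, with monomer composition, mass density, electron counts, the
#' tabulated ELF energy range, and the single (unique-FEG) Wigner-Seitz
#' radius used when each polymer is approximated by one homogeneous electron
#' gas. PMMA is registered as C5H8O2 (the methyl methacrylate repeat unit):
#' the source table prints (C8H8O2)n, but its printed 54/40 electron counts
#' match C5H8O2 exactly, so the corrected formula is used and the printed
#' string kept alongside.
#'
#' @param name optional single material name (\code{"PE"}, \code{"PS"},
#'   \code{"P2VP"}, \code{"PA"}, \code{"PMMA"}, \code{"PI"}); if omitted the
#'   full named list is returned.
#' @return A named list of \code{\link{material}} objects, or one material.
#' @examples
#' builtin_materials("PMMA")
#' @export
builtin_materials <- function(name = NULL) {
  mats <- list(
    PE = material("PE", c(C = 2, H = 4), density = 0.93,
                  unique_rs = 1.75, elf_range = c(0, 790)),
    PS = material("PS", c(C = 8, H = 8), density = 1.06,
                  unique_rs = 1.66, elf_range = c(0, 670),
                  total_electrons = 56, valence_electrons = 40),
    P2VP = material("P2VP", c(C = 7, H = 7, N = 1), density = 1.15,
                    unique_rs = 1.66, elf_range = c(0, 1000),
                    total_electrons = 56, valence_electrons = 40),
    PA = material("PA", c(C = 2, H = 2), density = 1.36,
                  unique_rs = 1.62, elf_range = c(0, 1000),
                  total_electrons = 14, valence_electrons = 10),
    PMMA = material("PMMA", c(C = 5, H = 8, O = 2), density = 1.19,
                    unique_rs = 1.74, elf_range = c(0, 3000),
                    formula_printed = "(C8H8O2)n",
                    total_electrons = 54, valence_electrons = 40),
    PI = material("PI", c(C = 22, H = 10, N = 2, O = 5), density = 1.42,
                  unique_rs = 1.61, elf_range = c(0, 8000),
                  total_electrons = 196, valence_electrons = 138)
  )
  if (is.null(name)) return(mats)
  if (!name %in% names(mats)) {
    stop("unknown built-in material '", name, "'; available: ",
         paste(names(mats), collapse = ", "))
  }
  mats[[name]]
}

#' Elemental stopping cross-section table
#'
#' @param element element symbol.
#' @param energies_keV increasing proton energies (keV).
#' @param scs SCS per atom in eV cm^2 / 10^15 atoms (>= 0).
#' @return An object of class \code{elemental_scs}.
#' @export
elemental_scs <- function(element, energies_keV, scs) {
  energies_keV <- as.numeric(energies_keV); scs <- as.numeric(scs)
  if (length(energies_keV) != length(scs)) stop("grid/value length mismatch")
  if (any(diff(energies_keV) <= 0)) stop("energy grid must be increasing")
  if (any(!is.finite(scs)) || any(scs < 0)) stop("SCS values must be >= 0")
  structure(list(element = element, energies_keV = energies_keV, scs = scs),
            class = "elemental_scs")
}

#' Read an elemental SCS table from TSV
#'
#' Expects header \code{E_keV scs_eVcm2_1e15} (or two unnamed numeric
#' columns); '#' lines are comments.
#'
#' @param path file path.
#' @param element element symbol for the table.
#' @return An \code{\link{elemental_scs}} object.
#' @export
read_elemental_scs <- function(path, element) {
  if (!file.exists(path)) stop("elemental SCS file not found: ", path)
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (ncol(d) < 2) stop("expected two columns in ", path)
  elemental_scs(element, d[[1]], d[[2]])
}

#' Write an elemental SCS table to TSV
#'
#' @param x an \code{\link{elemental_scs}} object.
#' @param path output path.
#' @export
write_elemental_scs <- function(x, path) {
  stopifnot(inherits(x, "elemental_scs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# elemental SCS for %s", x$element), con)
  writeLines("E_keV\tscs_eVcm2_1e15", con)
  writeLines(sprintf("%.6g\t%.6g", x$energies_keV, x$scs), con)
  invisible(path)
}

#' Bragg-rule combination of elemental stopping cross-sections
#'
#' The Bragg additivity rule: the SCS per monomer of a compound is the
#' stoichiometric sum of its constituents' atomic SCS,
#' \eqn{SCS_{monomer}(E) = \sum_i n_i\,SCS_i(E)}, and per atom the sum
#' divided by the atom count. Elemental tables with different grids are
#' interpolated linearly in log energy; the output grid is restricted to the
#' overlap of all input grids unless an explicit grid is given.
#'
#' @param tables list of \code{\link{elemental_scs}} objects covering every
#'   element in \code{composition}.
#' @param composition named atoms-per-monomer vector.
#' @param energies_keV optional output energy grid; must lie inside every
#'   elemental grid.
#' @return An object of class \code{scs_table} (see
#'   \code{\link{stopping_to_scs}}) with per-atom and per-monomer columns.
#' @export
bragg_combine <- function(tables, composition, energies_keV = NULL) {
  composition <- validate_composition(composition)
  names(tables) <- vapply(tables, function(t) t$element, character(1))
  missing <- setdiff(names(composition), names(tables))
  if (length(missing)) {
    stop("missing elemental SCS table(s) for: ", paste(missing, collapse = ", "))
  }
  lo <- max(vapply(tables[names(composition)], function(t) min(t$energies_keV), 0))
  hi <- min(vapply(tables[names(composition)], function(t) max(t$energies_keV), 0))
  if (is.null(energies_keV)) {
    grids <- lapply(tables[names(composition)], function(t) t$energies_keV)
    energies_keV <- sort(unique(unlist(grids)))
    energies_keV <- energies_keV[energies_keV >= lo & energies_keV <= hi]
  } else {
    if (any(energies_keV < lo) || any(energies_keV > hi)) {
      stop(sprintf("requested energies outside common grid [%.4g, %.4g] keV",
                   lo, hi))
    }
  }
  per_monomer <- numeric(length(energies_keV))
  for (el in names(composition)) {
    t <- tables[[el]]
    si <- stats::approx(log(t$energies_keV), t$scs, xout = log(energies_keV),
                        rule = 1)$y
    per_monomer <- per_monomer + composition[[el]] * si
  }
  n_atoms <- sum(composition)
  structure(list(
    energies_keV = energies_keV,
    scs_per_atom = per_monomer / n_atoms,
    scs_per_monomer = per_monomer,
    atoms_per_monomer = as.integer(n_atoms),
    label = paste0("Bragg rule: ",
                   paste0(names(composition), composition, collapse = ""))
  ), class = "scs_table")
}

#' Bragg-rule mean excitation energy of a compound
#'
#' The electron-weighted logarithmic average that the additivity rule
#' implies for the Bethe formula:
#' \deqn{\ln I = \frac{\sum_i n_i Z_i \ln I_i}{\sum_i n_i Z_i}.}
#' Invariant under duplicating the repeat unit, and bounded by the elemental
#' I values.
#'
#' @param composition named atoms-per-monomer vector.
#' @param elemental_I named numeric vector of elemental mean excitation
#'   energies in eV (one per element in the composition).
#' @return Compound mean excitation energy in eV.
#' @examples
#' bragg_mean_excitation(c(H = 2, O = 1), c(H = 19.2, O = 105.0))  # ~74.8
#' @export
bragg_mean_excitation <- function(composition, elemental_I) {
  composition <- validate_composition(composition)
  missing <- setdiff(names(composition), names(elemental_I))
  if (length(missing)) {
    stop("missing elemental I value(s) for: ", paste(missing, collapse = ", "))
  }
  I_i <- elemental_I[names(composition)]
  if (any(!is.finite(I_i)) || any(I_i <= 0)) stop("elemental I must be positive")
  w <- composition * element_lookup(names(composition), "Z")
  exp(sum(w * log(I_i)) / sum(w))
}

#' Read / write a materials registry config file
#'
#' The registry is a human-editable YAML file: one entry per material with
#' keys \code{composition} (element -> count), \code{density},
#' \code{unique_rs} and optional \code{elf_range}.
#'
#' @param path file path.
#' @return \code{read_materials}: named list of \code{\link{material}}s.
#' @export
read_materials <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    material(nm, unlist(r$composition), density = r$density,
             unique_rs = if (is.null(r$unique_rs)) NA_real_ else r$unique_rs,
             elf_range = if (is.null(r$elf_range)) NULL else as.numeric(r$elf_range))
  })
  stats::setNames(out, names(raw))
}

#' @rdname read_materials
#' @param materials named list of \code{\link{material}} objects to write.
#' @export
write_materials <- function(materials, path) {
  raw <- lapply(materials, function(m) {
    out <- list(composition = as.list(m$composition), density = m$density)
    if (is.finite(m$unique_rs)) out$unique_rs <- m$unique_rs
    if (!is.null(m$elf_range)) out$elf_range <- m$elf_range
    out
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}
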