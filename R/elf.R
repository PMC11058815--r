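#' Energy-loss-function object
#'
#' An \code{elf} object holds the optical-limit energy-loss function
#' Im[-1/eps(omega)] of a material on a strictly increasing grid of
#' excitation energies. It is the material's excitation spectrum at zero
#' momentum transfer and the input to the Penn decomposition.
#'
#' @param energies_eV strictly increasing excitation energies in eV, all > 0,
#'   at least 8 points.
#' @param values ELF values (dimensionless, >= 0, finite), same length.
#' @param label free-text provenance tag.
#' @return An object of class \code{elf}: a list with fields
#'   \code{energies_eV}, \code{values}, \code{label}.
#' @export
elf <- function(energies_eV, values, label = "unlabelled") {
  energies_eV <- as.numeric(energies_eV)
  values <- as.numeric(values)
  if (length(energies_eV) != length(values)) {
    stop("energies and values must have equal length")
  }
  if (length(energies_eV) < 8) stop("ELF needs at least 8 grid points")
  if (any(!is.finite(energies_eV)) || any(energies_eV <= 0)) {
    stop("ELF energies must be positive and finite")
  }
  if (any(diff(energies_eV) <= 0)) {
    stop("ELF energy grid must be strictly increasing (no duplicates)")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("ELF values must be non-negative and finite")
  }
  structure(list(energies_eV = energies_eV, values = values,
                 label = as.character(label)[1]),
            class = "elf")
}

#' @export
print.elf <- function(x, ...) {
  cat(sprintf("ELF '%s': %d points, %.3g-%.4g eV, max %.4g at %.3g eV\n",
              x$label, length(x$energies_eV),
              min(x$energies_eV), max(x$energies_eV),
              max(x$values), x$energies_eV[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.elf <- function(x, ..., log = "x") {
  graphics::plot(x$energies_eV, x$values, type = "l", log = log,
                 xlab = "excitation energy (eV)", ylab = "ELF",
                 main = x$label, ...)
  invisible(x)
}

#' Read an energy-loss function from a two-column text file
#'
#' Expects whitespace-separated rows \code{energy_eV elf_value}; lines
#' starting with \code{#} are comments. Rows are sorted by energy; duplicate
#' energies, negative ELF values and unparsable rows are rejected with the
#' offending line number.
#'
#' @param path path to the file.
#' @param label provenance label; defaults to the file name.
#' @return An \code{\link{elf}} object.
#' @export
read_elf <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("ELF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 8) stop("ELF file needs at least 8 data rows: ", path)
  e <- numeric(length(idx)); v <- numeric(length(idx))
  for (i in seq_along(idx)) {
    toks <- strsplit(trimws(lines[idx[i]]), "\\s+")[[1]]
    if (length(toks) < 2) {
      stop(sprintf("line %d of %s: expected two columns", idx[i], path))
    }
    ei <- suppressWarnings(as.numeric(toks[1]))
    vi <- suppressWarnings(as.numeric(toks[2]))
    if (!is.finite(ei) || !is.finite(vi)) {
      stop(sprintf("line %d of %s: unparsable numbers '%s'", idx[i], path,
                   lines[idx[i]]))
    }
    if (vi < 0) {
      stop(sprintf("line %d of %s: negative ELF value %.4g", idx[i], path, vi))
    }
    e[i] <- ei; v[i] <- vi
  }
  ord <- order(e)
  e <- e[ord]; v <- v[ord]
  if (any(diff(e) == 0)) {
    stop("duplicate energies in ELF file: ", path)
  }
  elf(e, v, label = label)
}

#' Write an energy-loss function to a two-column text file
#'
#' @param x an \code{\link{elf}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_elf <- function(x, path) {
  stopifnot(inherits(x, "elf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ELF table: %s", x$label),
               "# energy_eV elf"), con)
  writeLines(sprintf("%.12g %.12g", x$energies_eV, x$values), con)
  invisible(path)
}

#' Drude oscillator set for synthetic energy-loss functions
#'
#' A sum of Drude terms
#' \deqn{ELF(\omega) = \sum_i A_i \gamma_i \omega /
#'       [(\omega^2-\omega_i^2)^2 + (\gamma_i\omega)^2]}
#' (all quantities in Hartree atomic units). This is the standard
#' optical-data practice for modelling measured ELFs and has closed-form sum
#' rules, which makes it the package's test fixture generator:
#' \eqn{\int_0^\infty \omega\,ELF\,d\omega = (\pi/2)\sum_i A_i} (f-sum) and
#' \eqn{\int_0^\infty ELF/\omega\,d\omega = (\pi/2)\sum_i A_i/\omega_i^2}
#' (screening sum). The single-oscillator case with \eqn{A = \omega_0^2}
#' reproduces the exact Drude-dielectric ELF with perfect screening.
#'
#' @param A oscillator weights (Hartree^2, > 0).
#' @param omega0 oscillator centres (Hartree, > 0).
#' @param gamma damping widths (Hartree, > 0).
#' @return An object of class \code{drude_set}.
#' @export
drude_set <- function(A, omega0, gamma) {
  A <- as.numeric(A); omega0 <- as.numeric(omega0); gamma <- as.numeric(gamma)
  n <- length(A)
  if (n == 0) stop("empty oscillator set")
  if (length(omega0) != n || length(gamma) != n) {
    stop("A, omega0, gamma must have equal length")
  }
  if (any(A <= 0) || any(omega0 <= 0) || any(gamma <= 0)) {
    stop("all oscillator parameters must be positive")
  }
  structure(list(A = A, omega0 = omega0, gamma = gamma), class = "drude_set")
}

#' Evaluate a Drude oscillator set
#'
#' @param osc a \code{\link{drude_set}}.
#' @param omega_ha frequencies in Hartree.
#' @return ELF values (dimensionless).
#' @export
drude_elf_values <- function(osc, omega_ha) {
  stopifnot(inherits(osc, "drude_set"))
  out <- numeric(length(omega_ha))
  for (i in seq_along(osc$A)) {
    out <- out + osc$A[i] * osc$gamma[i] * omega_ha /
      ((omega_ha^2 - osc$omega0[i]^2)^2 + (osc$gamma[i] * omega_ha)^2)
  }
  out
}

#' Closed-form sum rules of a Drude oscillator set
#'
#' @param osc a \code{\link{drude_set}}.
#' @return A list with \code{f_sum} = \eqn{(\pi/2)\sum A_i} (Hartree^2) and
#'   \code{screening_sum} = \eqn{(\pi/2)\sum A_i/\omega_i^2} (dimensionless).
#' @export
drude_sum_rules <- function(osc) {
  stopifnot(inherits(osc, "drude_set"))
  list(f_sum = (pi / 2) * sum(osc$A),
       screening_sum = (pi / 2) * sum(osc$A / osc$omega0^2))
}

#' Generate a synthetic energy-loss function from Drude oscillators
#'
#' @param osc a \code{\link{drude_set}}.
#' @param omega_min_eV,omega_max_eV grid range in eV (both > 0).
#' @param n number of grid points (>= 8).
#' @param spacing \code{"log"} or \code{"linear"} grid.
#' @param label provenance label.
#' @return An \code{\link{elf}} object.
#' @export
synth_elf <- function(osc, omega_min_eV, omega_max_eV, n = 600,
                      spacing = c("log", "linear"), label = "synthetic Drude") {
  stopifnot(inherits(osc, "drude_set"))
  spacing <- match.arg(spacing)
  if (omega_min_eV <= 0 || omega_max_eV <= omega_min_eV) {
    stop("need 0 < omega_min < omega_max")
  }
  grid_eV <- if (spacing == "log") {
    exp(seq(log(omega_min_eV), log(omega_max_eV), length.out = n))
  } else {
    seq(omega_min_eV, omega_max_eV, length.out = n)
  }
  vals <- drude_elf_values(osc, ev_to_hartree(grid_eV))
  elf(grid_eV, vals, label = label)
}

# internal: resample an ELF for moment integrals: a log-spaced grid merged
# with the native grid points, so narrow native features are never lost
elf_log_resample <- function(x, n = 2000L) {
  e <- x$energies_eV
  g <- sort(unique(c(e, exp(seq(log(e[1]), log(e[length(e)]),
                                length.out = n)))))
  v <- stats::approx(e, x$values, xout = g, rule = 2)$y
  list(energies_eV = g, values = v)
}

#' Effective electron count from the f-sum rule
#'
#' Evaluates the running f-sum
#' \deqn{Z_{eff}(\omega_{max}) = \frac{2}{\pi\,\Omega_m^2}
#'       \int_0^{\omega_{max}} \omega'\,ELF(\omega')\,d\omega'}
#' with \eqn{\Omega_m^2 = 4\pi n_{monomer}} set by the monomer number density
#' of \code{material}, so the result counts electrons per monomer probed by
#' the ELF up to \code{omega_max}. Non-decreasing in \code{omega_max};
#' approaches the total electron count when the ELF extends over all shells.
#'
#' @param x an \code{\link{elf}} object.
#' @param material a \code{\link{material}} object (density and composition).
#' @param omega_max_eV upper integration limit; must lie within the ELF grid.
#'   Defaults to the grid top.
#' @param n_resample log-resampling density for the quadrature.
#' @return Effective electrons per monomer (numeric scalar).
#' @export
f_sum_effective_electrons <- function(x, material,
                                      omega_max_eV = max(x$energies_eV),
                                      n_resample = 2000L) {
  stopifnot(inherits(x, "elf"), inherits(material, "material"))
  e <- x$energies_eV
  if (omega_max_eV < e[1] || omega_max_eV > e[length(e)] * (1 + 1e-12)) {
    stop(sprintf("omega_max %.4g eV outside ELF grid [%.4g, %.4g]",
                 omega_max_eV, e[1], e[length(e)]))
  }
  rs <- elf_log_resample(x, n_resample)
  keep <- rs$energies_eV <= omega_max_eV
  w_ha <- ev_to_hartree(rs$energies_eV[keep])
  if (sum(keep) < 2) return(0)
  integral <- pracma::trapz(w_ha, w_ha * rs$values[keep])
  omega_m2 <- 4 * pi * monomer_number_density_au(material)
  2 / (pi * omega_m2) * integral
}

#' Mean excitation energy from the logarithmic ELF moment
#'
#' The Bethe-sum-rule logarithmic moment
#' \deqn{\ln I = \frac{\int \omega\,ELF(\omega)\ln\omega\,d\omega}
#'              {\int \omega\,ELF(\omega)\,d\omega}}
#' evaluated over the full ELF grid (core-excitation tails included).
#' Invariant under uniform rescaling of the ELF. For a narrow single
#' oscillator at \eqn{\omega_0} this tends to \eqn{\omega_0}; for two
#' equal-mass narrow oscillators, to the geometric mean of their centres.
#'
#' @param x an \code{\link{elf}} object with nonzero mass.
#' @param n_resample log-resampling density for the quadrature.
#' @return Mean excitation energy I in eV.
#' @export
mean_excitation_energy <- function(x, n_resample = 2000L) {
  stopifnot(inherits(x, "elf"))
  rs <- elf_log_resample(x, n_resample)
  w <- rs$energies_eV        # eV; the log moment is unit-covariant
  f <- w * rs$values
  denom <- pracma::trapz(w, f)
  if (denom <= 0) stop("degenerate input: ELF has zero mass")
  exp(pracma::trapz(w, f * log(w)) / denom)
}

#' Penn weight of an energy-loss function
#'
#' The Penn decomposition assigns to each plasmon frequency the weight
#' \deqn{g(\omega_p) = \frac{2}{\pi\,\omega_p}\,ELF(\omega_p)}
#' (atomic units). For a physically normalised ELF the perfect-screening
#' sum rule \eqn{\int ELF/\omega\, d\omega = \pi/2} makes
#' \eqn{\int g\,d\omega_p \approx 1}; the integral is reported as
#' \code{integral_mass} and deviations from 1 flag ELF truncation or
#' normalisation problems. The weight is not renormalised by default.
#'
#' @param x an \code{\link{elf}} object.
#' @return An object of class \code{penn_weight}: list with \code{omega_p}
#'   (Hartree grid), \code{g} (Hartree^-1), \code{integral_mass}, and the
#'   source \code{label}.
#' @export
penn_weight <- function(x) {
  stopifnot(inherits(x, "elf"))
  w_ha <- ev_to_hartree(x$energies_eV)
  g <- 2 / (pi * w_ha) * x$values
  structure(list(omega_p = w_ha, g = g,
                 integral_mass = pracma::trapz(w_ha, g),
                 label = x$label),
            class = "penn_weight")
}

#' @export
print.penn_weight <- function(x, ...) {
  cat(sprintf(
    "Penn weight for '%s': %d points, omega_p %.4g-%.4g Ha, integral mass %.4f\n",
    x$label, length(x$omega_p), min(x$omega_p), max(x$omega_p),
    x$integral_mass))
  invisible(x)
}
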