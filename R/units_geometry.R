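#' Plasmon frequency of a free-electron gas
#'
#' The collective oscillation frequency of a homogeneous electron gas with
#' Wigner-Seitz radius \code{r_s}: \eqn{\omega_p = \sqrt{3}\, r_s^{-3/2}}
#' (atomic units), equivalent to \eqn{\omega_p^2 = 4\pi n_0} with
#' \eqn{(4\pi/3) r_s^3 n_0 = 1}.
#'
#' @param r_s Wigner-Seitz radius in bohr (> 0). Vectorised.
#' @return Plasmon frequency in Hartree.
#' @examples
#' plasmon_frequency(1)            # sqrt(3)
#' hartree_to_ev(plasmon_frequency(1.75))
#' @export
plasmon_frequency <- function(r_s) {
  if (any(!is.finite(r_s)) || any(r_s <= 0)) {
    stop("r_s must be positive and finite")
  }
  sqrt(3) * r_s^(-1.5)
}

#' Wigner-Seitz radius from a plasmon frequency
#'
#' Inverse of \code{\link{plasmon_frequency}}:
#' \eqn{r_s = (\sqrt{3}/\omega_p)^{2/3}}.
#'
#' @param omega_p plasmon frequency in Hartree (> 0). Vectorised.
#' @return Wigner-Seitz radius in bohr.
#' @export
wigner_seitz_from_omega <- function(omega_p) {
  if (any(!is.finite(omega_p)) || any(omega_p <= 0)) {
    stop("omega_p must be positive and finite")
  }
  (sqrt(3) / omega_p)^(2 / 3)
}

#' Electron count of a neutral jellium cluster
#'
#' A jellium sphere of radius \code{R_cl} at bulk density set by \code{r_s}
#' holds \eqn{N_e = (R_{cl}/r_s)^3} electrons (rounded to the nearest
#' integer).
#'
#' @param R_cl cluster radius in bohr (> 0).
#' @param r_s Wigner-Seitz radius in bohr (> 0).
#' @return Integer electron count.
#' @examples
#' electrons_in_cluster(8.38, 1.00)  # 588
#' @export
electrons_in_cluster <- function(R_cl, r_s) {
  if (any(!is.finite(R_cl)) || any(R_cl <= 0)) stop("R_cl must be positive")
  if (any(!is.finite(r_s)) || any(r_s <= 0)) stop("r_s must be positive")
  as.integer(round((R_cl / r_s)^3))
}

#' Jellium geometry bundle
#'
#' Collects the mutually consistent jellium parameters for a cluster:
#' density, plasmon frequency and electron count from \code{r_s} and
#' \code{R_cl}.
#'
#' @param r_s Wigner-Seitz radius (bohr).
#' @param R_cl cluster radius (bohr).
#' @return A list of class \code{jellium_geometry} with fields \code{r_s},
#'   \code{n0} (bohr^-3), \code{omega_p} (Hartree), \code{R_cl} and
#'   \code{N_e}.
#' @export
jellium_geometry <- function(r_s, R_cl) {
  if (!is.finite(r_s) || r_s <= 0) stop("r_s must be positive")
  if (!is.finite(R_cl) || R_cl <= 0) stop("R_cl must be positive")
  n0 <- 3 / (4 * pi * r_s^3)
  out <- list(
    r_s = r_s, n0 = n0,
    omega_p = plasmon_frequency(r_s),
    R_cl = R_cl,
    N_e = electrons_in_cluster(R_cl, r_s)
  )
  if (out$N_e < 1) stop("cluster smaller than one electron: increase R_cl")
  structure(out, class = "jellium_geometry")
}

#' @export
print.jellium_geometry <- function(x, ...) {
  cat(sprintf(
    "jellium: r_s = %.3f bohr, n0 = %.5g bohr^-3, omega_p = %.4f Ha (%.2f eV), R_cl = %.2f bohr, N_e = %d\n",
    x$r_s, x$n0, x$omega_p, hartree_to_ev(x$omega_p), x$R_cl, x$N_e
  ))
  invisible(x)
}

#' Proton velocity from kinetic energy
#'
#' Converts proton kinetic energy to velocity in atomic units. The
#' non-relativistic form \eqn{v = \sqrt{2T/M_p}} is adequate below about
#' 10 MeV (beta <= 0.145, error < 1\%); the relativistic form
#' \eqn{v = c\beta} with \eqn{\gamma = 1 + T/(M_p c^2)} is exact at all
#' energies.
#'
#' @param kinetic_energy_eV proton kinetic energy in eV (> 0). Vectorised.
#' @param relativistic logical; use relativistic kinematics.
#' @return Velocity in atomic units (bohr / atomic time unit).
#' @export
proton_velocity <- function(kinetic_energy_eV, relativistic = FALSE) {
  if (any(!is.finite(kinetic_energy_eV)) || any(kinetic_energy_eV < 0)) {
    stop("kinetic energy must be non-negative")
  }
  T_ha <- ev_to_hartree(kinetic_energy_eV)
  mp <- pennstop_constants$m_proton
  if (!relativistic) {
    return(sqrt(2 * T_ha / mp))
  }
  c_au <- pennstop_constants$c_au
  gamma <- 1 + T_ha / (mp * c_au^2)
  beta <- sqrt(1 - 1 / gamma^2)
  c_au * beta
}

#' Proton kinetic energy from velocity
#'
#' Inverse of \code{\link{proton_velocity}} (non-relativistic form).
#'
#' @param v velocity in atomic units.
#' @return Kinetic energy in eV.
#' @export
proton_energy_from_velocity <- function(v) {
  if (any(!is.finite(v)) || any(v < 0)) stop("velocity must be non-negative")
  hartree_to_ev(0.5 * pennstop_constants$m_proton * v^2)
}
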