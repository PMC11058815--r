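#' Physical constants used throughout the package
#'
#' Single source of truth for unit conversions. All internal computation is in
#' Hartree atomic units; user-facing I/O is in eV/keV/MeV, g/cm3 and
#' eV cm^2 / 10^15 atoms.
#'
#' @format A named list:
#' \describe{
#'   \item{hartree_eV}{1 Hartree in eV (27.211386)}
#'   \item{bohr_cm}{1 bohr in cm (0.529177e-8)}
#'   \item{m_proton}{proton mass in electron masses (1836.152)}
#'   \item{c_au}{speed of light in atomic units (137.036)}
#'   \item{avogadro}{Avogadro constant (mol^-1)}
#'   \item{K_bethe}{Bethe stopping constant, MeV cm^2 / mol (0.307075)}
#'   \item{me_c2_MeV}{electron rest energy in MeV}
#'   \item{mp_c2_MeV}{proton rest energy in MeV}
#' }
#' @export
pennstop_constants <- list(
  hartree_eV = 27.211386,
  bohr_cm    = 0.529177e-8,
  m_proton   = 1836.152,
  c_au       = 137.036,
  avogadro   = 6.02214076e23,
  K_bethe    = 0.307075,
  me_c2_MeV  = 0.51099895,
  mp_c2_MeV  = 938.27209
)

#' Convert energies between eV and Hartree
#'
#' @param x numeric vector of energies.
#' @return Numeric vector in the target unit.
#' @export
ev_to_hartree <- function(x) x / pennstop_constants$hartree_eV

#' @rdname ev_to_hartree
#' @export
hartree_to_ev <- function(x) x * pennstop_constants$hartree_eV

#' Convert lengths between bohr and cm
#'
#' @param x numeric vector of lengths.
#' @return Numeric vector in the target unit.
#' @export
bohr_to_cm <- function(x) x * pennstop_constants$bohr_cm

#' @rdname bohr_to_cm
#' @export
cm_to_bohr <- function(x) x / pennstop_constants$bohr_cm

# internal: atomic-unit stopping (Hartree/bohr) -> eV/cm
stopping_au_to_ev_cm <- function(s) {
  s * pennstop_constants$hartree_eV / pennstop_constants$bohr_cm
}
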