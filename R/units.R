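#' Physical constants and unit conversion
#'
#' The package computes in Hartree atomic units internally (the
#' charge-equilibration equations and the Coulomb kernel then carry no
#' prefactor), while files use the conventional Angstrom / eV units.
#' Conversion factors are CODATA 2018 values.
#'
#' @format A named list with elements `bohr_ang` (Angstrom per Bohr),
#'   `hartree_ev` (eV per Hartree) and `ha_bohr_ev_ang` (eV/Angstrom per
#'   Hartree/Bohr).
#' @export
units_au <- list(
  bohr_ang   = 0.529177210903,
  hartree_ev = 27.211386245988,
  ha_bohr_ev_ang = 27.211386245988 / 0.529177210903
)

# Covalent radii in Angstrom (Cordero et al. 2008 single-bond values),
# used as default Gaussian charge-density widths.
.covalent_radii_ang <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
  N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
  Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Ti = 1.60, Fe = 1.32, Ni = 1.24, Cu = 1.32,
  Zn = 1.22, Br = 1.20, Ag = 1.45, I = 1.39, Pt = 1.36, Au = 1.36
)

#' Covalent radius of an element
#'
#' Default source of the per-element Gaussian charge-density width
#' \eqn{\sigma_i}: the tabulated covalent radius.
#'
#' @param element character vector of element symbols.
#' @param unit `"bohr"` (default, the internal unit) or `"ang"`.
#' @return numeric vector of radii.
#' @export
covalent_radius <- function(element, unit = c("bohr", "ang")) {
  unit <- match.arg(unit)
  r <- .covalent_radii_ang[element]
  if (anyNA(r)) {
    stop("no covalent radius tabulated for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  r <- unname(r)
  if (unit == "bohr") r / units_au$bohr_ang else r
}
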