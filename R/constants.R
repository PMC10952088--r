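# Physical constants and unit conversions. Canonical internal units are
# Angstrom and picosecond; conversions happen exactly once, at I/O boundaries.

#' Physical constants used throughout the package
#'
#' A named list of physical constants and unit-conversion factors:
#' \describe{
#'   \item{bohr_to_angstrom}{Bohr radius in Angstrom (0.529177...).}
#'   \item{au_time_to_ps}{atomic unit of time in picoseconds.}
#'   \item{k_boltzmann}{Boltzmann constant in J/K.}
#'   \item{avogadro}{Avogadro constant in 1/mol.}
#'   \item{xi_cubic}{dimensionless hydrodynamic self-interaction constant of a
#'     cubic lattice (2.837297), used by the finite-size diffusion correction;
#'     recomputable from scratch with [ewald_self_constant()].}
#'   \item{mass_O, mass_H, mass_D}{atomic masses in amu.}
#'   \item{molar_mass_h2o, molar_mass_d2o}{molar masses in g/mol.}
#'   \item{A2ps_to_1e9m2s}{factor from Angstrom^2/ps to 1e-9 m^2/s (= 10).}
#' }
#'
#' @examples
#' aq_constants$xi_cubic
#' @export
aq_constants <- list(
  bohr_to_angstrom = 0.529177210903,
  au_time_to_ps    = 2.4188843265857e-5,
  k_boltzmann      = 1.380649e-23,
  avogadro         = 6.02214076e23,
  xi_cubic         = 2.837297,
  mass_O           = 15.999,
  mass_H           = 1.008,
  mass_D           = 2.014,
  molar_mass_h2o   = 18.015,
  molar_mass_d2o   = 20.027,
  A2ps_to_1e9m2s   = 10
)
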