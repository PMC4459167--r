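#' Unit conversion constants
#'
#' Internal unit system: lengths in Angstrom, energies in kcal/mol, masses
#' in amu, charges in elementary charge units. These constants convert to
#' the SI-flavoured units results are reported in.
#'
#' @format A named list:
#' \describe{
#'   \item{kcalmol_to_J}{1 kcal/mol expressed in joules per molecule
#'     (4184 / N_A = 6.9477e-21 J).}
#'   \item{coulomb_k}{Coulomb constant in kcal.A/(mol.e^2): 332.0637.}
#'   \item{kcalmol_A3_to_GPa}{kcal/mol/A^3 to GPa (x 6.9477).}
#'   \item{kcalmol_A2_to_mJm2}{kcal/mol/A^2 to mJ/m^2 (x 694.77).}
#'   \item{amu_A3_to_gcc}{amu/A^3 to g/cc (x 1.66054).}
#' }
#' @export
fk_units <- list(
  kcalmol_to_J      = 6.9477e-21,
  coulomb_k         = 332.0637,
  kcalmol_A3_to_GPa = 6.9477,
  kcalmol_A2_to_mJm2 = 694.77,
  amu_A3_to_gcc     = 1.66054
)
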