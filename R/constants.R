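# Physical constants and unit conventions used throughout the package.
# Units: energy kcal/mol, length Angstrom, time ps, mass amu, temperature K.

# Boltzmann constant, kcal/mol/K (7 significant digits).
.kB <- 1.987204e-3

# 1 kcal/mol expressed in amu * A^2 / ps^2 (converts energy-unit forces to
# accelerations in the Langevin integrator).
.AKMA <- 418.4

#' Thermal energy k_B * T
#'
#' Boltzmann constant used by the package is 1.987204e-3 kcal/mol/K, so at
#' the default simulation temperature of 310 K, `kBT(310)` is about
#' 0.616 kcal/mol.
#'
#' @param temperature Temperature in Kelvin (> 0).
#' @return Thermal energy in kcal/mol.
#' @examples
#' kBT(310)
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}
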