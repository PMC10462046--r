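#' Physical constants and unit conventions
#'
#' All quantities in the package use a fixed unit system: lengths in nm,
#' times in ns, energies in kJ/mol, temperatures in K. The membrane normal
#' is the +z axis.
#'
#' @name units
#' @keywords internal
NULL

#' Boltzmann constant in kJ mol^-1 K^-1
#' @export
KB <- 0.008314462618

#' Thermal energy k_B * T
#'
#' @param temperature temperature in K
#' @return k_B T in kJ/mol
#' @examples
#' kBT(310) # ~2.5775 kJ/mol, the thermal energy at physiological temperature
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB * temperature
}
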