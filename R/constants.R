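## Physical constants and unit conversions.
## Internal units everywhere: kcal/mol (energy), Angstrom (length),
## ps (time), Da = g/mol (mass).

#' Boltzmann constant in kcal/mol/K
#' @keywords internal
KB_KCAL <- 0.0019872041

## 1 kcal = 4.184 kJ (thermochemical calorie), exact.
KJ_PER_KCAL <- 4.184

## Acceleration conversion: 1 (kcal/mol/A) force acting on 1 Da gives
## 4184 J/mol / 1e-10 m / 1e-3 kg/mol = 4.184e16 m/s^2 = 418.4 A/ps^2.
ACC_KCAL_DA <- 418.4

## Avogadro's number and Dalton in kg, for SI frequency conversion.
N_AVOGADRO <- 6.02214076e23
DA_KG <- 1.66053906660e-27

#' Convert a force constant from kJ/mol/A^2 to kcal/mol/A^2
#'
#' Umbrella force constants are conventionally quoted in kJ/mol/A^2
#' (e.g. 5 or 10 kJ/mol/A^2); all internal energies are kcal/mol.
#'
#' @param k numeric, force constant in kJ/mol/A^2
#' @return force constant in kcal/mol/A^2
#' @export
#' @examples
#' kj_to_kcal(5) # 1.1951...
kj_to_kcal <- function(k) k / KJ_PER_KCAL

#' Thermal energy kB*T in kcal/mol
#'
#' @param temperature temperature in K
#' @return kB*T in kcal/mol
#' @export
kbt <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCAL * temperature
}
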