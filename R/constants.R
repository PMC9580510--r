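#' Physical constants used throughout the package
#'
#' CODATA 2018 values (the SI-exact defining constants), centralized so that
#' every rate expression, tunneling factor and unit conversion draws on one
#' table. Energies are handled internally in kcal/mol using the
#' thermochemical calorie (1 cal = 4.184 J) and the conversion
#' 627.5095 kcal/mol per hartree.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{kB}{Boltzmann constant, J/K}
#'     \item{h}{Planck constant, J s}
#'     \item{NA}{Avogadro constant, 1/mol}
#'     \item{c_cm}{speed of light, cm/s}
#'     \item{R_J}{molar gas constant, J/(mol K)}
#'     \item{R_kcal}{molar gas constant, kcal/(mol K)}
#'     \item{cal_J}{thermochemical calorie, J}
#'     \item{hartree_kcal}{kcal/mol per hartree}
#'     \item{molar_volume_1atm}{ideal-gas molar volume at 298.15 K / 1 atm, L/mol,
#'       as conventionally used in the 1 atm to 1 M standard-state shift}
#'   }
#' @export
#' @examples
#' physical_constants()$R_kcal * 298.15 * log(10)  # RT ln10, ~1.364 kcal/mol
physical_constants <- function() {
  kB <- 1.380649e-23
  h <- 6.62607015e-34
  NAv <- 6.02214076e23
  list(
    kB = kB,
    h = h,
    `NA` = NAv,
    c_cm = 2.99792458e10,
    R_J = kB * NAv,
    R_kcal = kB * NAv / 4184,
    cal_J = 4.184,
    hartree_kcal = 627.5095,
    molar_volume_1atm = 24.46
  )
}

.const <- physical_constants()

#' Convert energies between hartree and kcal/mol
#'
#' Lossless linear conversions by the constant 627.5095 kcal/mol per hartree.
#'
#' @param x numeric vector of energies.
#' @return numeric vector in the target unit.
#' @export
#' @examples
#' kcal_to_hartree(hartree_to_kcal(-100.123456))
hartree_to_kcal <- function(x) x * .const$hartree_kcal

#' @rdname hartree_to_kcal
#' @export
kcal_to_hartree <- function(x) x / .const$hartree_kcal

#' Standard-state shift between 1 atm and 1 M reference states
#'
#' Gas-phase thermochemistry is commonly reported at a 1 atm standard state
#' while solution kinetics use 1 M. Converting a reaction (or activation)
#' free energy adds RT ln(24.46) per unit change in molecularity, 24.46 L/mol
#' being the ideal-gas molar volume at 298.15 K. For a bimolecular activation
#' step (two reactants, one transition state) `molecularity_change = -1`,
#' lowering the barrier by about 1.89 kcal/mol at 298.15 K.
#'
#' @param dG free energy in kcal/mol at the source standard state.
#' @param temperature temperature in K.
#' @param molecularity_change moles of species gained going from the initial
#'   to the final side of the process (-1 for a bimolecular association).
#' @return free energy in kcal/mol at the 1 M standard state; the inverse
#'   conversion is obtained by negating `molecularity_change`.
#' @export
standard_state_correction <- function(dG, temperature = 298.15,
                                      molecularity_change = -1) {
  stopifnot(temperature > 0)
  dG + molecularity_change * .const$R_kcal * temperature *
    log(.const$molar_volume_1atm)
}
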