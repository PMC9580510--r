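#' Stokes-Einstein diffusion coefficient
#'
#' D = kB T / (6 pi eta a) for a spherical solute of hydrodynamic radius a
#' in a continuum of viscosity eta (stick boundary conditions).
#'
#' @param temperature temperature, K.
#' @param viscosity dynamic viscosity, Pa s.
#' @param radius hydrodynamic radius, m.
#' @return diffusion coefficient, m^2/s (vectorized).
#' @export
#' @examples
#' stokes_einstein_diffusivity(298.15, 8.9e-4, 2e-10)  # ~1.23e-9 m^2/s
stokes_einstein_diffusivity <- function(temperature, viscosity, radius) {
  if (any(temperature <= 0) || any(viscosity <= 0) || any(radius <= 0))
    rk_error("temperature, viscosity and radius must be > 0",
             "radkin_validation_error")
  .const$kB * temperature / (6 * pi * viscosity * radius)
}

#' Smoluchowski diffusion-limited rate constant
#'
#' k_D = 4 pi R_AB D_AB N_A for an encounter distance R_AB and mutual
#' diffusion coefficient D_AB = D_A + D_B, converted from m^3 mol^-1 s^-1
#' to M^-1 s^-1 (factor 1000 L/m^3). No electrostatic (Debye) factor is
#' applied: the hydroperoxyl radical is neutral, so the encounter is
#' uncharged on one side in every channel treated here.
#'
#' @param reaction_distance encounter distance R_AB, m (> 0).
#' @param mutual_diffusivity D_A + D_B, m^2/s (> 0).
#' @return diffusion-limited rate constant, M^-1 s^-1.
#' @export
#' @examples
#' smoluchowski_rate(4e-10, 2e-9)   # ~6.05e9 M^-1 s^-1
smoluchowski_rate <- function(reaction_distance, mutual_diffusivity) {
  if (any(reaction_distance <= 0) || any(mutual_diffusivity <= 0))
    rk_error("reaction distance and diffusivity must be > 0",
             "radkin_validation_error")
  4 * pi * reaction_distance * mutual_diffusivity * .const$`NA` * 1000
}

#' Collins-Kimball apparent rate constant
#'
#' Interpolates between activation control and the diffusion limit:
#' k_app = k_act * k_D / (k_act + k_D). Symmetric in its arguments and never
#' larger than either; an infinite `k_diffusion` recovers the pure
#' activation-controlled rate. Both rates zero returns zero.
#'
#' @param k_activation activation-controlled (TST) rate constant,
#'   M^-1 s^-1 (>= 0).
#' @param k_diffusion diffusion-limited rate constant, M^-1 s^-1 (>= 0;
#'   `Inf` disables the diffusion limit).
#' @return apparent rate constant, M^-1 s^-1 (vectorized).
#' @export
collins_kimball <- function(k_activation, k_diffusion) {
  if (any(k_activation < 0) || any(k_diffusion < 0))
    rk_error("rate constants must be >= 0", "radkin_validation_error")
  n <- max(length(k_activation), length(k_diffusion))
  ka <- rep_len(k_activation, n)
  kd <- rep_len(k_diffusion, n)
  out <- numeric(n)
  inf_d <- is.infinite(kd)
  out[inf_d] <- ka[inf_d]
  zero <- !inf_d & (ka + kd) == 0
  rest <- !inf_d & !zero
  out[rest] <- ka[rest] * kd[rest] / (ka[rest] + kd[rest])
  out
}

#' Diffusion-limited rate constant for a bimolecular encounter
#'
#' Convenience chain: per-reactant Stokes-Einstein diffusivities, mutual
#' diffusivity by addition, then the Smoluchowski rate at the encounter
#' distance (default: sum of the radii).
#'
#' @param temperature temperature, K.
#' @param viscosity solvent viscosity, Pa s.
#' @param radius_A,radius_B hydrodynamic radii of the two reactants, m.
#' @param reaction_distance encounter distance, m; defaults to
#'   `radius_A + radius_B`.
#' @return diffusion-limited rate constant, M^-1 s^-1.
#' @export
diffusion_rate <- function(temperature, viscosity, radius_A, radius_B,
                           reaction_distance = radius_A + radius_B) {
  DA <- stokes_einstein_diffusivity(temperature, viscosity, radius_A)
  DB <- stokes_einstein_diffusivity(temperature, viscosity, radius_B)
  smoluchowski_rate(reaction_distance, DA + DB)
}

#' Marcus-theory activation barrier for electron transfer
#'
#' dG_activation = (lambda / 4) * (1 + dG_reaction / lambda)^2, the
#' parabolic free-energy relation for outer-sphere single electron
#' transfer. The reorganization energy lambda may be supplied directly or
#' derived from the vertical electron-transfer energy as
#' lambda = dE_SET - dG_reaction. In the inverted region
#' (dG_reaction < -lambda) the barrier is clamped at 0 with a warning, the
#' conventional treatment for thermal SET screening.
#'
#' @param dG_reaction reaction free energy of the SET step, kcal/mol.
#' @param lambda_reorg reorganization energy lambda, kcal/mol (> 0), or
#'   NULL to derive it from `dE_SET`.
#' @param dE_SET vertical electron-transfer energy, kcal/mol (used only
#'   when `lambda_reorg` is NULL).
#' @return activation free energy, kcal/mol (vectorized).
#' @export
#' @examples
#' marcus_barrier(0, 20)      # lambda / 4 = 5
#' marcus_barrier(5.25, 20)   # 7.9695
marcus_barrier <- function(dG_reaction, lambda_reorg = NULL, dE_SET = NULL) {
  if (is.null(lambda_reorg)) {
    if (is.null(dE_SET))
      rk_error("either lambda_reorg or dE_SET must be supplied",
               "radkin_validation_error")
    lambda_reorg <- dE_SET - dG_reaction
  }
  if (any(lambda_reorg <= 0))
    rk_error("reorganization energy must be > 0", "radkin_validation_error")
  dGa <- (lambda_reorg / 4) * (1 + dG_reaction / lambda_reorg)^2
  inverted <- dG_reaction < -lambda_reorg
  if (any(inverted)) {
    warning(sprintf(
      "%d channel(s) in the Marcus inverted region: barrier clamped at 0",
      sum(inverted)))
    dGa[inverted] <- 0
  }
  dGa
}
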