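#' Screen reaction channels by exergonicity
#'
#' Channels with a positive reaction free energy are omitted from the
#' kinetic analysis: even if fast, they are easily reversible and
#' contribute negligibly to scavenging capacity. The inequality is strict
#' (dG_reaction = 0 is retained). Channels marked `present = FALSE` are
#' removed silently; they never existed for that species.
#'
#' @param channels a `radkin_channels` data.frame (see [channel_table()]).
#' @return a list with `retained` (channels entering the kinetics),
#'   `omitted` (endergonic channels, with a `reason` column), and `report`
#'   (a per-row account of every decision).
#' @export
screen_exergonic <- function(channels) {
  channels <- validate_channel_table(as.data.frame(channels))
  bad <- channels$present & is.na(channels$dG_reaction)
  if (any(bad))
    rk_error(sprintf(
      "channel %s/%s site %s is present but has no dG_reaction",
      channels$species_label[bad][1], channels$mechanism[bad][1],
      channels$site[bad][1]), "radkin_validation_error")
  decision <- ifelse(!channels$present, "absent",
                     ifelse(channels$dG_reaction > 0, "omitted (endergonic)",
                            "retained"))
  report <- data.frame(
    species_label = channels$species_label, mechanism = channels$mechanism,
    site = channels$site, solvent = channels$solvent,
    dG_reaction = channels$dG_reaction, decision = decision,
    stringsAsFactors = FALSE)
  omitted <- channels[decision == "omitted (endergonic)", , drop = FALSE]
  if (nrow(omitted)) omitted$reason <- "dG_reaction > 0"
  retained <- channels[decision == "retained", , drop = FALSE]
  class(retained) <- class(channels)
  list(retained = retained, omitted = omitted, report = report)
}

#' Per-channel rate constants with tunneling and diffusion corrections
#'
#' For each retained channel: FHT channels get an Eyring rate from the
#' tabulated activation free energy with the selected tunneling correction
#' (Eckart barriers taken as forward = dG_activation and reverse =
#' dG_activation - dG_reaction); SET channels get a Marcus barrier from
#' dG_reaction and a reorganization energy, with no tunneling (kappa = 1).
#' Every bimolecular rate is then capped by the Collins-Kimball
#' interpolation against the solvent's diffusion limit.
#'
#' @param channels a `radkin_channels` data.frame of retained channels
#'   (typically `screen_exergonic(...)$retained`).
#' @param solvents a named list of [solvent_environment()] objects keyed by
#'   the solvent identifiers appearing in `channels`.
#' @param tunneling "eckart", "wigner" or "none".
#' @param radius_A,radius_B hydrodynamic radii of antioxidant and radical,
#'   m. The 2.0 Angstrom default is a fixture-scale placeholder and should
#'   be overridden for real solutes.
#' @param reaction_distance encounter distance, m (default sum of radii).
#' @param lambda_reorg Marcus reorganization energy for SET channels,
#'   kcal/mol (required if any SET channel is present).
#' @param apply_standard_state if TRUE, lower each activation free energy
#'   by RT ln(24.46), the 1 atm to 1 M shift for a bimolecular step; leave
#'   FALSE when the tabulated energetics are already at the 1 M standard
#'   state.
#' @return a data.frame of class `radkin_rates`: the channel identifiers
#'   plus `kappa`, `k_tst` (tunneling included), `k_diffusion` and
#'   `k_apparent`, all in M^-1 s^-1.
#' @export
channel_rates <- function(channels, solvents,
                          tunneling = c("eckart", "wigner", "none"),
                          radius_A = 2e-10, radius_B = 2e-10,
                          reaction_distance = radius_A + radius_B,
                          lambda_reorg = NULL,
                          apply_standard_state = FALSE) {
  tunneling <- match.arg(tunneling)
  channels <- as.data.frame(channels)
  if (!nrow(channels)) {
    warning("no channels to rate: returning an empty breakdown")
    out <- cbind(channels[, c("mechanism", "site", "solvent", "species_label"),
                          drop = FALSE],
                 data.frame(kappa = numeric(0), k_tst = numeric(0),
                            k_diffusion = numeric(0), k_apparent = numeric(0)))
    class(out) <- c("radkin_rates", "data.frame")
    return(out)
  }
  need <- setdiff(unique(channels$solvent), names(solvents))
  if (length(need))
    rk_error(sprintf("no solvent environment defined for: %s",
                     paste(need, collapse = ", ")), "radkin_validation_error")
  n <- nrow(channels)
  kappa <- k_tst <- k_diff <- numeric(n)
  for (i in seq_len(n)) {
    sv <- solvents[[channels$solvent[i]]]
    Tt <- sv$temperature
    if (channels$mechanism[i] == "SET") {
      dGa <- marcus_barrier(channels$dG_reaction[i], lambda_reorg)
      kap <- 1
    } else {
      dGa <- channels$dG_activation[i]
      if (is.na(dGa))
        rk_error(sprintf("FHT channel %s site %s has no dG_activation",
                         channels$species_label[i], channels$site[i]),
                 "radkin_validation_error")
      kap <- switch(tunneling,
        none = 1,
        wigner = wigner_tunneling(channels$imaginary_frequency[i], Tt),
        eckart = eckart_tunneling(channels$imaginary_frequency[i],
                                  dGa, dGa - channels$dG_reaction[i], Tt))
    }
    if (apply_standard_state)
      dGa <- standard_state_correction(dGa, Tt, molecularity_change = -1)
    kappa[i] <- kap
    k_tst[i] <- eyring_rate(dGa, Tt, channels$symmetry_number[i], kap)
    k_diff[i] <- diffusion_rate(Tt, sv$viscosity, radius_A, radius_B,
                                reaction_distance)
  }
  out <- cbind(channels[, c("mechanism", "site", "solvent", "species_label"),
                        drop = FALSE],
               data.frame(kappa = kappa, k_tst = k_tst, k_diffusion = k_diff,
                          k_apparent = collins_kimball(k_tst, k_diff)))
  rownames(out) <- NULL
  class(out) <- c("radkin_rates", "data.frame")
  out
}

#' Total rate coefficient of one species in one solvent
#'
#' The arithmetic sum of the apparent per-channel rate constants of a single
#' (species, solvent) pair.
#'
#' @param k_apparent numeric vector of apparent channel rate constants,
#'   M^-1 s^-1, all belonging to one species in one solvent.
#' @return k_total, M^-1 s^-1 (0 with a warning for an empty collection).
#' @export
k_total <- function(k_apparent) {
  if (!length(k_apparent)) {
    warning("no channels: k_total = 0")
    return(0)
  }
  if (any(k_apparent < 0))
    rk_error("channel rate constants must be >= 0", "radkin_validation_error")
  sum(k_apparent)
}

#' Fraction-weighted overall rate coefficient at a given pH
#'
#' Each coexisting acid-base species contributes its molar fraction times
#' its total rate coefficient, k_f = f * k_total; the overall coefficient is
#' the sum over species. With a single species at f = 1 this reduces to
#' k_overall = k_total (the lipid-phase case, where only the neutral form
#' exists).
#'
#' @param species_totals named numeric vector: k_total per species label,
#'   M^-1 s^-1.
#' @param fractions named numeric vector of molar fractions; names must
#'   cover `species_totals` (a species absent from `fractions` is taken as
#'   f = 0 with a warning); fractions must be non-negative and sum to at
#'   most 1 (+1e-9).
#' @return a list with `k_f` (named vector, f * k_total per species) and
#'   `k_overall` (their sum), M^-1 s^-1.
#' @export
#' @examples
#' k_overall_at_pH(c(H3W = 1.99e4, `H2W-` = 1.35e8),
#'                 c(H3W = 0.942, `H2W-` = 0.058))
k_overall_at_pH <- function(species_totals, fractions) {
  if (is.null(names(species_totals)) || is.null(names(fractions)))
    rk_error("species_totals and fractions must be named",
             "radkin_validation_error")
  if (any(fractions < 0))
    rk_error("fractions must be >= 0", "radkin_validation_error")
  if (sum(fractions) > 1 + 1e-9)
    rk_error("fractions sum to more than 1", "radkin_validation_error")
  missing <- setdiff(names(species_totals), names(fractions))
  if (length(missing)) {
    warning(sprintf("no molar fraction for species %s: treated as f = 0",
                    paste(missing, collapse = ", ")))
    fractions[missing] <- 0
  }
  f <- fractions[names(species_totals)]
  k_f <- setNames(as.numeric(f) * as.numeric(species_totals),
                  names(species_totals))
  list(k_f = k_f, k_overall = sum(k_f))
}

#' Branching ratios of the channels of one species
#'
#' Gamma_i = 100 * k_i / sum(k), the percentage contribution of each
#' channel to its species' total rate coefficient. Ratios sum to 100.
#'
#' @param k_apparent numeric vector of apparent channel rate constants
#'   (optionally named by site), all of one species in one solvent.
#' @return named numeric vector of percentages summing to 100.
#' @export
branching_ratios <- function(k_apparent) {
  if (any(k_apparent < 0))
    rk_error("channel rate constants must be >= 0", "radkin_validation_error")
  tot <- sum(k_apparent)
  if (!length(k_apparent) || tot == 0)
    rk_error("branching ratios undefined: k_total = 0",
             "radkin_validation_error")
  100 * k_apparent / tot
}

#' Fold-change of an overall rate coefficient against a reference antioxidant
#'
#' @param k_overall rate coefficient of the compound, M^-1 s^-1.
#' @param reference_k rate coefficient of the reference antioxidant,
#'   M^-1 s^-1 (> 0).
#' @param label reference name for the report.
#' @return a list with `label`, `fold` (unrounded) and `fold_rounded`
#'   (nearest integer, the conventional way such comparisons are quoted).
#' @export
#' @examples
#' compare_to_reference(4.84e5, 9.70e4, "Trolox")   # ~5x
compare_to_reference <- function(k_overall, reference_k, label = "reference") {
  if (reference_k <= 0)
    rk_error("reference_k must be > 0", "radkin_validation_error")
  fold <- k_overall / reference_k
  list(label = label, fold = fold, fold_rounded = round(fold))
}
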