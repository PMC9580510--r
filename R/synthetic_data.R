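#' Default solvent environments
#'
#' Water and pentyl ethanoate (the conventional pseudo-lipid medium) at
#' 298.15 K, with dynamic viscosities 8.91e-4 and 8.62e-4 Pa s
#' respectively. Both are overridable wherever a solvent list is accepted.
#'
#' @param pH pH of the aqueous phase.
#' @param temperature temperature, K.
#' @return named list of [solvent_environment()] objects.
#' @export
default_solvents <- function(pH = 7.4, temperature = 298.15) {
  list(
    water = solvent_environment("water", 8.91e-4, temperature, "aqueous",
                                pH = pH),
    `pentyl ethanoate` = solvent_environment("pentyl ethanoate", 8.62e-4,
                                             temperature, "lipid")
  )
}

#' Specification of a synthetic antioxidant fixture
#'
#' Describes a fictional polyprotic phenolic antioxidant reacting with a
#' neutral radical: how many acidic O-H sites it has, the pKa values those
#' sites must reproduce, and the ranges the per-channel energetics are
#' drawn from. Defaults mirror a triprotic phenol of the kind studied in
#' hydroperoxyl-scavenging work: pKa steps at 8.71 / 14.59 / 25.11,
#' H-transfer barriers of 5-18 kcal/mol, reaction free energies between
#' -14 and +1 kcal/mol, transition-state imaginary frequencies of
#' 1000-3500 cm^-1, and a 20 kcal/mol SET reorganization energy.
#'
#' @param n_sites number of acidic sites (1-4).
#' @param pka_targets strictly increasing pKa values, length `n_sites`.
#' @param barrier_range (min, max) of FHT activation free energies,
#'   kcal/mol; must sit above the largest possible reaction free energy so
#'   every drawn transition state lies above both endpoints.
#' @param reaction_dG_range (min, max) of FHT reaction free energies,
#'   kcal/mol.
#' @param imaginary_freq_range (min, max) of imaginary wavenumbers, cm^-1.
#' @param set_lambda Marcus reorganization energy for the SET channels,
#'   kcal/mol.
#' @param pH pH at which ground-truth speciation and overall rates are
#'   evaluated.
#' @param pka_reference pKa of the reference acid used to build the
#'   isodesmic inputs.
#' @param temperature temperature, K.
#' @param seed integer seed; mandatory, there is no implicit randomness.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_sites = 3,
                         pka_targets = c(8.71, 14.59, 25.11),
                         barrier_range = c(5, 18),
                         reaction_dG_range = c(-14, 1),
                         imaginary_freq_range = c(1000, 3500),
                         set_lambda = 20,
                         pH = 7.4,
                         pka_reference = 4.75,
                         temperature = 298.15,
                         seed) {
  if (missing(seed) || !is.numeric(seed))
    rk_error("an integer seed is mandatory", "radkin_validation_error")
  if (n_sites < 1 || n_sites > 4)
    rk_error("n_sites must be between 1 and 4", "radkin_validation_error")
  if (length(pka_targets) != n_sites)
    rk_error("pka_targets must have one value per site",
             "radkin_validation_error")
  if (n_sites >= 2 && any(diff(pka_targets) <= 0))
    rk_error("pka_targets must be strictly increasing",
             "radkin_validation_error")
  for (rng in list(barrier_range, reaction_dG_range, imaginary_freq_range))
    if (length(rng) != 2 || rng[1] > rng[2])
      rk_error("ranges must be (min, max) with min <= max",
               "radkin_validation_error")
  if (barrier_range[1] < max(0, reaction_dG_range[2]))
    rk_error(
      "barrier_range must sit above max(0, reaction_dG_range[2]) so drawn transition states are valid",
      "radkin_validation_error")
  if (set_lambda <= 0)
    rk_error("set_lambda must be > 0", "radkin_validation_error")
  structure(list(n_sites = n_sites, pka_targets = pka_targets,
                 barrier_range = barrier_range,
                 reaction_dG_range = reaction_dG_range,
                 imaginary_freq_range = imaginary_freq_range,
                 set_lambda = set_lambda, pH = pH,
                 pka_reference = pka_reference, temperature = temperature,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.state_label <- function(n_sites, i) {
  core <- if (n_sites - i > 0) {
    if (n_sites - i > 1) paste0("H", n_sites - i, "A") else "HA"
  } else "A"
  if (i == 0) core else if (i == 1) paste0(core, "-") else
    paste0(core, i, "-")
}

#' Generate an internally consistent synthetic antioxidant system
#'
#' Draws a complete fixture from a [fixture_spec()]: a species table, a
#' reaction-channel table (FHT channels per site in water and in the lipid
#' phase, endergonic SET channels in water, explicit `present = FALSE` rows
#' for the anion's deprotonated site and the lipid SET path, and one lipid
#' FHT channel forced endergonic so the screening stage is exercised),
#' isodesmic proton-exchange energies constructed by inverting the pKa
#' closed form, and a ground-truth block.
#'
#' The ground truth (per-channel rate constants with Wigner tunneling and
#' the Collins-Kimball diffusion cap, per-species totals, molar fractions,
#' fraction-corrected coefficients, overall rate coefficients and branching
#' ratios) is computed inside this generator by straight-line arithmetic
#' from locally bound constants -- deliberately not by the pipeline
#' functions -- so round-trip tests compare two independent evaluations.
#' Fixture kinetics use the Wigner correction because it has a closed form
#' that any checker can re-derive to full precision.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, the species, channel and
#'   isodesmic tables, a `fixture.yaml` header (including the seed) and a
#'   `ground_truth.yaml` report are written there in the same formats
#'   [read_species_table()] and [read_channel_table()] read.
#' @return a list of class `radkin_fixture` with `spec`, `species`,
#'   `channels`, `isodesmic`, `solvents`, `radius_A`, `radius_B`, and
#'   `ground_truth`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_sites
  Tt <- spec$temperature
  solvents <- default_solvents(pH = spec$pH, temperature = Tt)
  aq <- "water"; lp <- "pentyl ethanoate"

  labels <- vapply(0:n, function(i) .state_label(n, i), character(1))
  sp_aq <- species_table(labels, charge = -(0:n), protonation_index = 0:n,
                         solvent = aq,
                         G = round(stats::runif(n + 1, -650, -600), 6))
  sp_lp <- species_table(labels[1], charge = 0L, protonation_index = 0L,
                         solvent = lp,
                         G = round(stats::runif(1, -650, -600), 6))
  species <- rbind(sp_aq, sp_lp)
  class(species) <- class(sp_aq)

  isodesmic <- data.frame(
    site = seq_len(n),
    pka_reference = spec$pka_reference,
    dG_exchange = dG_exchange_for_pka(spec$pka_targets, spec$pka_reference, Tt),
    stringsAsFactors = FALSE)

  draw <- function(rng, m) stats::runif(m, rng[1], rng[2])
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  # FHT channels: neutral in both solvents, first anion in water only,
  # the anion's site 1 (the first site deprotonated) marked absent
  for (sv in c(aq, lp)) {
    states <- if (sv == aq) 0:1 else 0L
    for (i in states) {
      for (s in seq_len(n)) {
        absent <- (i == 1L && s == 1L)
        if (absent) {
          add(mechanism = "FHT", site = as.character(s), solvent = sv,
              species_label = labels[i + 1], dG_reaction = NA_real_,
              dG_activation = NA_real_, imaginary_frequency = NA_real_,
              symmetry_number = 1L, present = FALSE)
        } else {
          dG <- draw(spec$reaction_dG_range, 1)
          if (sv == lp && i == 0L && s == 1L)    # forced endergonic channel
            dG <- stats::runif(1, 0.1, max(0.8, spec$reaction_dG_range[2]))
          add(mechanism = "FHT", site = as.character(s), solvent = sv,
              species_label = labels[i + 1], dG_reaction = dG,
              dG_activation = draw(spec$barrier_range, 1),
              imaginary_frequency = draw(spec$imaginary_freq_range, 1),
              symmetry_number = 1L, present = TRUE)
        }
      }
    }
  }
  # SET channels: endergonic in water (screened downstream), absent in lipid
  for (i in 0:1)
    add(mechanism = "SET", site = "SET", solvent = aq,
        species_label = labels[i + 1],
        dG_reaction = stats::runif(1, 2, 35), dG_activation = NA_real_,
        imaginary_frequency = NA_real_, symmetry_number = 1L, present = TRUE)
  add(mechanism = "SET", site = "SET", solvent = lp,
      species_label = labels[1], dG_reaction = NA_real_,
      dG_activation = NA_real_, imaginary_frequency = NA_real_,
      symmetry_number = 1L, present = FALSE)
  channels <- validate_channel_table(do.call(rbind, rows))

  radius <- 2e-10                       # fixture-scale fallback radius
  ground_truth <- .fixture_oracle(spec, channels, solvents, radius)

  fx <- structure(list(spec = spec, species = species, channels = channels,
                       isodesmic = isodesmic, solvents = solvents,
                       radius_A = radius, radius_B = radius,
                       ground_truth = ground_truth),
                  class = "radkin_fixture")
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

# Straight-line ground-truth arithmetic with locally bound constants:
# intentionally independent of the package's rate functions.
.fixture_oracle <- function(spec, channels, solvents, radius) {
  kB <- 1.380649e-23; h <- 6.62607015e-34; NAv <- 6.02214076e23
  cc <- 2.99792458e10; Rk <- kB * NAv / 4184
  Tt <- spec$temperature
  keep <- channels$present & channels$mechanism == "FHT" &
    channels$dG_reaction <= 0
  ch <- channels[keep, , drop = FALSE]
  kap <- 1 + (h * cc * ch$imaginary_frequency / (kB * Tt))^2 / 24
  k_tst <- ch$symmetry_number * kap * (kB * Tt / h) *
    exp(-ch$dG_activation / (Rk * Tt))
  eta <- vapply(ch$solvent, function(s) solvents[[s]]$viscosity, numeric(1))
  kD <- 4 * pi * (2 * radius) * (2 * kB * Tt / (6 * pi * eta * radius)) *
    NAv * 1000
  k_app <- k_tst * kD / (k_tst + kD)
  per_channel <- cbind(ch[, c("mechanism", "site", "solvent", "species_label")],
                       data.frame(kappa = kap, k_tst = k_tst,
                                  k_diffusion = kD, k_apparent = k_app))
  rownames(per_channel) <- NULL
  key <- paste(ch$species_label, ch$solvent, sep = " @ ")
  totals <- vapply(split(k_app, key), sum, numeric(1))
  gamma <- lapply(split(seq_along(k_app), key), function(ix)
    setNames(100 * k_app[ix] / sum(k_app[ix]), ch$site[ix]))
  # speciation at the stated pH from the target pKa values
  lg <- c(0, cumsum(spec$pH - spec$pka_targets))
  f <- 10^(lg - max(lg)); f <- f / sum(f)
  labels <- vapply(0:spec$n_sites, function(i) .state_label(spec$n_sites, i),
                   character(1))
  names(f) <- labels
  aq_keys <- grep(" @ water$", names(totals), value = TRUE)
  aq_lab <- sub(" @ water$", "", aq_keys)
  k_f <- setNames(f[aq_lab] * totals[aq_keys], aq_lab)
  lp_keys <- grep(" @ water$", names(totals), value = TRUE, invert = TRUE)
  list(per_channel = per_channel,
       k_total = totals,
       fractions = f,
       k_f = k_f,
       k_overall_aqueous = sum(k_f),
       k_overall_lipid = sum(totals[lp_keys]),
       gamma = gamma,
       endergonic_channels = channels[channels$present &
                                        channels$dG_reaction > 0 &
                                        !is.na(channels$dG_reaction), ,
                                      drop = FALSE])
}

#' Write a fixture to disk
#'
#' Emits `species.tsv`, `channels.tsv`, `isodesmic.tsv`, a `fixture.yaml`
#' header recording the generating spec (including the seed), and
#' `ground_truth.yaml`. Numeric formatting is fixed at 17 significant
#' digits, so the same spec always produces byte-identical files.
#'
#' @param fx a `radkin_fixture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_species_table(fx$species, file.path(dir, "species.tsv"))
  write_channel_table(fx$channels, file.path(dir, "channels.tsv"))
  iso <- fx$isodesmic
  iso$dG_exchange <- fmt_num(iso$dG_exchange)
  write.table(iso, file.path(dir, "isodesmic.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hdr <- fx$spec
  class(hdr) <- NULL
  yaml::write_yaml(hdr, file.path(dir, "fixture.yaml"),
                   precision = 17L)
  gt <- fx$ground_truth
  gt$per_channel <- as.list(as.data.frame(gt$per_channel))
  gt$endergonic_channels <-
    as.list(as.data.frame(gt$endergonic_channels))
  gt$k_total <- as.list(gt$k_total)
  gt$fractions <- as.list(gt$fractions)
  gt$k_f <- as.list(gt$k_f)
  gt$gamma <- lapply(gt$gamma, as.list)
  yaml::write_yaml(gt, file.path(dir, "ground_truth.yaml"), precision = 17L)
  invisible(dir)
}
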