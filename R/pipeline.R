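#' Assemble a pipeline configuration
#'
#' Two execution modes keep "reproduce the published arithmetic" separate
#' from "recompute from raw energetics":
#' \describe{
#'   \item{internal}{starts from raw channel energetics: speciation (from
#'     pKa values or isodesmic inputs), exergonicity screening, TST rates
#'     with tunneling, diffusion corrections, then aggregation.}
#'   \item{as-printed}{starts from published molar fractions and per-species
#'     total rate coefficients and performs only the fraction-weighted
#'     aggregation and reference comparisons, exactly as such tables are
#'     combined in print.}
#' }
#'
#' @param mode "internal" or "as-printed".
#' @param species species table (`radkin_species` or file path), internal
#'   mode; used to map species labels to protonation indices.
#' @param channels channel table (`radkin_channels` or file path), internal
#'   mode.
#' @param pkas strictly increasing pKa values (internal mode; alternative
#'   to `isodesmic`).
#' @param isodesmic data.frame with columns `dG_exchange` and
#'   `pka_reference` (internal mode; converted through [pka_isodesmic()]).
#' @param solvents named list of [solvent_environment()] objects; defaults
#'   to [default_solvents()] at `pH`.
#' @param pH pH for the aqueous phase.
#' @param temperature temperature, K.
#' @param tunneling "eckart", "wigner" or "none".
#' @param radius_A,radius_B,reaction_distance diffusion geometry, m.
#' @param lambda_reorg Marcus reorganization energy for SET channels,
#'   kcal/mol.
#' @param apply_standard_state logical; see [channel_rates()].
#' @param fractions named molar fractions (as-printed mode).
#' @param k_totals named per-species aqueous k_total values, M^-1 s^-1
#'   (as-printed mode).
#' @param k_total_lipid lipid-phase k_total (= k_overall there), M^-1 s^-1
#'   (as-printed mode, optional).
#' @param references list of reference antioxidants, each a list with
#'   `label`, `k` (M^-1 s^-1) and `scope` ("aqueous" or "lipid").
#' @return a list of class `radkin_config`.
#' @export
pipeline_config <- function(mode = c("internal", "as-printed"),
                            species = NULL, channels = NULL,
                            pkas = NULL, isodesmic = NULL,
                            solvents = NULL, pH = 7.4, temperature = 298.15,
                            tunneling = c("eckart", "wigner", "none"),
                            radius_A = 2e-10, radius_B = 2e-10,
                            reaction_distance = radius_A + radius_B,
                            lambda_reorg = NULL,
                            apply_standard_state = FALSE,
                            fractions = NULL, k_totals = NULL,
                            k_total_lipid = NULL, references = list()) {
  mode <- match.arg(mode)
  tunneling <- match.arg(tunneling)
  if (mode == "as-printed") {
    if (is.null(fractions) || is.null(k_totals))
      rk_error("as-printed mode requires user-supplied fractions and k_totals",
               "radkin_validation_error")
  } else {
    if (is.null(channels))
      rk_error("internal mode requires raw channel energetics",
               "radkin_validation_error")
    if (is.null(pkas) && is.null(isodesmic))
      rk_error("internal mode requires pkas or isodesmic inputs",
               "radkin_validation_error")
  }
  if (is.null(solvents)) solvents <- default_solvents(pH, temperature)
  structure(list(mode = mode, species = species, channels = channels,
                 pkas = pkas, isodesmic = isodesmic, solvents = solvents,
                 pH = pH, temperature = temperature, tunneling = tunneling,
                 radius_A = radius_A, radius_B = radius_B,
                 reaction_distance = reaction_distance,
                 lambda_reorg = lambda_reorg,
                 apply_standard_state = apply_standard_state,
                 fractions = fractions, k_totals = k_totals,
                 k_total_lipid = k_total_lipid, references = references),
            class = "radkin_config")
}

#' Configuration for a generated fixture
#'
#' Convenience wrapper building an internal-mode [pipeline_config()] from a
#' [generate_fixture()] result, using the fixture's solvents, geometry and
#' isodesmic inputs, with Wigner tunneling (the correction the fixture's
#' ground truth is defined with).
#'
#' @param fx a `radkin_fixture`.
#' @return a `radkin_config`.
#' @export
fixture_config <- function(fx) {
  stopifnot(inherits(fx, "radkin_fixture"))
  pipeline_config(mode = "internal", species = fx$species,
                  channels = fx$channels, isodesmic = fx$isodesmic,
                  solvents = fx$solvents, pH = fx$spec$pH,
                  temperature = fx$spec$temperature, tunneling = "wigner",
                  radius_A = fx$radius_A, radius_B = fx$radius_B,
                  lambda_reorg = fx$spec$set_lambda)
}

#' Read a pipeline configuration from a YAML file
#'
#' The config file is the single human-readable format tying the stages
#' together: mode, table paths (resolved relative to the config file),
#' solvent definitions (name, viscosity, polarity_class, pH), temperature,
#' tunneling selection, diffusion geometry, and -- for as-printed mode --
#' fractions, k_totals and reference antioxidants.
#'
#' @param path YAML file path.
#' @return a `radkin_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    rk_error(sprintf("config file not found: %s", path), "radkin_io_error")
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (!is.null(p) && !file.exists(p))
    file.path(base, p) else p
  solvents <- NULL
  if (!is.null(cfg$solvents))
    solvents <- setNames(lapply(cfg$solvents, function(s)
      solvent_environment(s$name, s$viscosity,
                          s$temperature %||% (cfg$temperature %||% 298.15),
                          s$polarity_class,
                          pH = s$pH)),
      vapply(cfg$solvents, `[[`, character(1), "name"))
  args <- list(
    mode = cfg$mode %||% "internal",
    species = resolve(cfg$species_table),
    channels = resolve(cfg$channel_table),
    pkas = cfg$pkas, solvents = solvents,
    pH = cfg$pH %||% 7.4, temperature = cfg$temperature %||% 298.15,
    tunneling = cfg$tunneling %||% "eckart",
    lambda_reorg = cfg$lambda_reorg,
    apply_standard_state = isTRUE(cfg$apply_standard_state),
    fractions = unlist(cfg$fractions), k_totals = unlist(cfg$k_totals),
    k_total_lipid = cfg$k_total_lipid,
    references = cfg$references %||% list())
  if (!is.null(cfg$isodesmic_table)) {
    iso_path <- resolve(cfg$isodesmic_table)
    args$isodesmic <- read.delim(iso_path, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  for (k in c("radius_A", "radius_B", "reaction_distance"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the antiradical-kinetics pipeline end to end
#'
#' Internal mode executes speciation, exergonicity screening, TST rates
#' with the selected tunneling correction, diffusion corrections and the
#' fraction-weighted aggregation; as-printed mode performs only the
#' aggregation arithmetic on published fractions and totals. Either way the
#' result is a report bundle carrying the speciation profile, the screening
#' report, the per-channel rate breakdown, per-species totals, k_f values,
#' overall rate coefficients per phase, branching ratios, reference
#' comparisons, and a log naming every default that was applied.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `radkin_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "radkin_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  warnings_seen <- character(0)
  withCallingHandlers(
    report <- if (config$mode == "as-printed")
      .run_as_printed(config, note) else .run_internal(config, note),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  report$warnings <- warnings_seen
  report$status <- if (length(warnings_seen)) "success with warnings"
    else "success"
  report$log <- log
  class(report) <- "radkin_report"
  report
}

.run_as_printed <- function(config, note) {
  note("mode: as-printed (published fractions and totals)")
  agg <- .stage("aggregation",
                k_overall_at_pH(config$k_totals, config$fractions))
  comparisons <- .stage("comparison", lapply(config$references, function(r) {
    k <- if (identical(r$scope, "lipid")) config$k_total_lipid
      else agg$k_overall
    if (is.null(k)) rk_error(
      sprintf("no %s-phase k_overall available for reference %s",
              r$scope, r$label), "radkin_validation_error")
    c(compare_to_reference(k, r$k, r$label), scope = r$scope %||% "aqueous")
  }))
  list(mode = "as-printed",
       fractions = config$fractions,
       k_total = config$k_totals,
       k_f = agg$k_f,
       k_overall = c(aqueous = agg$k_overall,
                     lipid = config$k_total_lipid %||% NA_real_),
       comparisons = comparisons)
}

.run_internal <- function(config, note) {
  species <- config$species
  if (is.character(species)) species <- read_species_table(species)
  channels <- config$channels
  if (is.character(channels)) channels <- read_channel_table(channels)

  pkas <- config$pkas
  if (is.null(pkas) && !is.null(config$isodesmic)) {
    iso <- config$isodesmic
    pkas <- sort(pka_isodesmic(iso$dG_exchange, iso$pka_reference,
                               config$temperature))
    note("pKa values from isodesmic inputs: %s",
         paste(sprintf("%.4f", pkas), collapse = ", "))
  }
  speciation <- .stage("speciation", molar_fractions(pkas, config$pH))

  screening <- .stage("screening", screen_exergonic(channels))
  note("screening: %d retained, %d omitted (endergonic), %d absent",
       nrow(screening$retained), nrow(screening$omitted),
       sum(!channels$present))

  note("tunneling: %s; radii %.3g / %.3g m; reaction distance %.3g m",
       config$tunneling, config$radius_A, config$radius_B,
       config$reaction_distance)
  for (sv in config$solvents)
    note("solvent %s: viscosity %.3g Pa s, T %.2f K%s", sv$name,
         sv$viscosity, sv$temperature,
         if (sv$polarity_class == "aqueous")
           sprintf(", pH %.2f", sv$pH) else " (lipid)")
  if (config$apply_standard_state)
    note("1 atm -> 1 M standard-state shift applied to activation energies")

  rates <- .stage("rates", channel_rates(
    screening$retained, config$solvents, tunneling = config$tunneling,
    radius_A = config$radius_A, radius_B = config$radius_B,
    reaction_distance = config$reaction_distance,
    lambda_reorg = config$lambda_reorg,
    apply_standard_state = config$apply_standard_state))

  .stage("aggregation", {
    idx_of <- if (!is.null(species))
      setNames(species$protonation_index, species$label) else NULL
    key <- paste(rates$species_label, rates$solvent, sep = " @ ")
    totals <- vapply(split(rates$k_apparent, key), k_total, numeric(1))
    gamma <- lapply(split(seq_len(nrow(rates)), key), function(ix)
      setNames(branching_ratios(rates$k_apparent[ix]), rates$site[ix]))
    k_overall <- c()
    k_f <- NULL
    for (sname in names(config$solvents)) {
      sv <- config$solvents[[sname]]
      keys <- grep(paste0(" @ ", sname, "$"), names(totals), value = TRUE)
      labs <- sub(paste0(" @ ", sname, "$"), "", keys)
      if (sv$polarity_class == "aqueous") {
        if (!length(keys)) { k_overall[sname] <- 0; next }
        if (is.null(idx_of)) rk_error(
          "a species table is needed to map labels to protonation states",
          "radkin_validation_error")
        fr <- speciation$fractions[as.character(idx_of[labs])]
        agg <- k_overall_at_pH(setNames(totals[keys], labs),
                               setNames(as.numeric(fr), labs))
        k_f <- agg$k_f
        k_overall[sname] <- agg$k_overall
      } else {
        k_overall[sname] <- if (length(keys)) sum(totals[keys]) else {
          warning(sprintf("no channels in %s: k_overall = 0", sname)); 0
        }
      }
    }
    if (!nrow(rates))
      warning("no channels survived screening: all rates are zero")
    comparisons <- lapply(config$references, function(r) {
      scope <- r$scope %||% "aqueous"
      sel <- vapply(config$solvents, function(s)
        s$polarity_class == scope, logical(1))
      if (!any(sel)) rk_error(sprintf("no %s solvent for reference %s",
                                      scope, r$label),
                              "radkin_validation_error")
      c(compare_to_reference(k_overall[[names(which(sel))[1]]], r$k, r$label),
        scope = scope)
    })
    list(mode = "internal", speciation = speciation, screening = screening,
         rates = rates, k_total = totals, k_f = k_f, gamma = gamma,
         k_overall = k_overall, comparisons = comparisons)
  })
}

#' @export
print.radkin_report <- function(x, ...) {
  cat(sprintf("radkin pipeline report (%s mode, %s)\n", x$mode, x$status))
  if (!is.null(x$speciation)) {
    cat("\nSpeciation:\n"); print(x$speciation)
  } else if (!is.null(x$fractions)) {
    cat("\nMolar fractions (as printed):\n")
    print(round(x$fractions, 3))
  }
  if (!is.null(x$screening)) {
    om <- x$screening$omitted
    cat(sprintf("\nScreening: %d channel(s) omitted as endergonic\n",
                nrow(om)))
    if (nrow(om))
      cat(sprintf("  %s %s site %s (%s): dG = %+.2f kcal/mol\n",
                  om$species_label, om$mechanism, om$site, om$solvent,
                  om$dG_reaction), sep = "")
  }
  cat("\nPer-species totals (M^-1 s^-1):\n")
  for (i in seq_along(x$k_total))
    cat(sprintf("  %-24s k_total = %.3g\n", names(x$k_total)[i],
                x$k_total[[i]]))
  if (!is.null(x$k_f)) {
    cat("Fraction-corrected coefficients (M^-1 s^-1):\n")
    for (i in seq_along(x$k_f))
      cat(sprintf("  %-24s k_f = %.3g\n", names(x$k_f)[i], x$k_f[[i]]))
  }
  cat("Overall rate coefficients (M^-1 s^-1):\n")
  for (i in seq_along(x$k_overall))
    if (is.finite(x$k_overall[[i]]))
      cat(sprintf("  %-24s k_overall = %.3g\n", names(x$k_overall)[i],
                  x$k_overall[[i]]))
  for (cmp in x$comparisons)
    cat(sprintf("  vs %s (%s): %.2f-fold (~%d times)\n", cmp$label,
                cmp$scope, cmp$fold, cmp$fold_rounded))
  if (length(x$warnings))
    cat(sprintf("\n%d warning(s) during the run\n", length(x$warnings)))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits delimited tables mirroring the shape of a published speciation /
#' screening / kinetics summary, plus `report.yaml` with unrounded values,
#' the screening log and the per-channel breakdown. Formatting is fixed, so
#' re-running an unchanged configuration reproduces byte-identical files.
#'
#' @param report a `radkin_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$speciation)) {
    f <- report$speciation$fractions
    tab1 <- data.frame(protonation_index = names(f),
                       fraction = fmt_num(as.numeric(f)),
                       fraction_display = sprintf("%.3f", f))
    write.table(tab1, file.path(dir, "speciation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$screening))
    write.table(report$screening$report, file.path(dir, "screening.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$rates)) {
    rt <- report$rates
    for (col in c("kappa", "k_tst", "k_diffusion", "k_apparent"))
      rt[[col]] <- fmt_num(rt[[col]])
    write.table(rt, file.path(dir, "rates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  summ <- data.frame(quantity = c(paste0("k_total: ", names(report$k_total)),
                                  paste0("k_f: ", names(report$k_f)),
                                  paste0("k_overall: ",
                                         names(report$k_overall))),
                     value = fmt_num(c(as.numeric(report$k_total),
                                       as.numeric(report$k_f),
                                       as.numeric(report$k_overall))),
                     display = sprintf("%.3g", c(as.numeric(report$k_total),
                                                 as.numeric(report$k_f),
                                                 as.numeric(report$k_overall))))
  write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yml <- list(mode = report$mode, status = report$status,
              k_total = as.list(report$k_total),
              k_f = as.list(report$k_f),
              k_overall = as.list(report$k_overall),
              comparisons = report$comparisons,
              log = report$log, warnings = report$warnings)
  if (!is.null(report$speciation))
    yml$fractions <- as.list(report$speciation$fractions)
  if (!is.null(report$gamma))
    yml$branching_ratios <- lapply(report$gamma, as.list)
  yaml::write_yaml(yml, file.path(dir, "report.yaml"), precision = 17L)
  invisible(dir)
}
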