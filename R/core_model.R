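#' @importFrom utils read.delim write.table
#' @importFrom stats setNames integrate
NULL

.species_cols <- c("label", "charge", "protonation_index", "solvent",
                   "G", "G_unit", "state_tag", "multiplicity")
.channel_cols <- c("mechanism", "site", "solvent", "species_label",
                   "dG_reaction", "dG_activation", "imaginary_frequency",
                   "symmetry_number", "present")

rk_error <- function(msg, class) {
  stop(structure(class = c(class, "radkin_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Construct a species table
#'
#' A species is one acid-base state of a compound in one solvent: a label
#' (e.g. "H3W", "H2W-"), its charge, the number of protons removed from the
#' fully protonated form (`protonation_index`: 0 for H3W, 1 for H2W-, ...),
#' and its Gibbs free energy with explicit unit and standard-state tags.
#' Energies are normalized to kcal/mol internally; the original unit tag is
#' retained only through the conversion being exactly invertible.
#'
#' @param label character vector of species identifiers.
#' @param charge integer vector, elementary charges.
#' @param protonation_index integer vector, >= 0.
#' @param solvent character vector of solvent identifiers.
#' @param G numeric Gibbs free energies.
#' @param G_unit "kcal/mol" or "hartree" (recycled).
#' @param state_tag standard state of `G`, "1M" or "1atm" (recycled;
#'   recorded, not altered -- see [standard_state_correction()]).
#' @param multiplicity positive integer spin multiplicities.
#' @return a `data.frame` of class `radkin_species` with `G` in kcal/mol.
#' @export
species_table <- function(label, charge, protonation_index, solvent, G,
                          G_unit = "kcal/mol", state_tag = "1M",
                          multiplicity = 1L) {
  df <- data.frame(label = as.character(label),
                   charge = as.integer(charge),
                   protonation_index = as.integer(protonation_index),
                   solvent = as.character(solvent),
                   G = as.numeric(G),
                   G_unit = rep_len(as.character(G_unit), length(label)),
                   state_tag = rep_len(as.character(state_tag), length(label)),
                   multiplicity = rep_len(as.integer(multiplicity), length(label)),
                   stringsAsFactors = FALSE)
  validate_species_table(df)
}

validate_species_table <- function(df) {
  missing <- setdiff(.species_cols, names(df))
  if (length(missing))
    rk_error(sprintf("species table is missing column(s): %s",
                     paste(missing, collapse = ", ")), "radkin_schema_error")
  bad_unit <- !df$G_unit %in% c("kcal/mol", "hartree")
  if (any(bad_unit))
    rk_error(sprintf("unknown energy unit '%s' (row %d)",
                     df$G_unit[bad_unit][1], which(bad_unit)[1]),
             "radkin_schema_error")
  if (any(!df$state_tag %in% c("1M", "1atm")))
    rk_error("state_tag must be '1M' or '1atm'", "radkin_schema_error")
  if (anyNA(df$G))
    rk_error(sprintf("unparseable energy in species table (row %d)",
                     which(is.na(df$G))[1]), "radkin_parse_error")
  if (any(df$protonation_index < 0))
    rk_error("protonation_index must be >= 0", "radkin_validation_error")
  if (any(df$multiplicity < 1))
    rk_error("multiplicity must be a positive integer", "radkin_validation_error")
  key <- paste(df$label, df$solvent, sep = "\r")
  if (anyDuplicated(key))
    rk_error(sprintf("duplicate (label, solvent) pair: (%s, %s)",
                     df$label[duplicated(key)][1],
                     df$solvent[duplicated(key)][1]), "radkin_schema_error")
  # one acid-base state per (label, solvent): the index must not collide
  # with a different label of the same solvent+index only through NA
  df$G <- ifelse(df$G_unit == "hartree", hartree_to_kcal(df$G), df$G)
  df$G_unit <- "kcal/mol"
  class(df) <- c("radkin_species", "data.frame")
  df
}

#' Read a species table from delimited text or a structured config
#'
#' Delimited files are tab- or comma-separated with a header row carrying the
#' fixed column names `label, charge, protonation_index, solvent, G, G_unit,
#' state_tag, multiplicity`. A structured config is a YAML file whose
#' `species:` key holds a list of records with the same fields. Energies in
#' hartree are converted to kcal/mol (627.5095 kcal/mol per hartree) on read.
#'
#' @param path file path.
#' @param format "delimited" or "config".
#' @return a `radkin_species` data.frame (empty, with a warning, for an
#'   empty file).
#' @export
read_species_table <- function(path, format = c("delimited", "config")) {
  format <- match.arg(format)
  if (!file.exists(path))
    rk_error(sprintf("file not found: %s", path), "radkin_io_error")
  if (format == "config") {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$species) || !length(cfg$species)) {
      warning("no species defined in config: returning an empty table")
      return(empty_species_table())
    }
    df <- do.call(rbind, lapply(cfg$species, function(sp)
      as.data.frame(sp[.species_cols[.species_cols %in% names(sp)]],
                    stringsAsFactors = FALSE)))
    for (col in c("G_unit", "state_tag", "multiplicity"))
      if (is.null(df[[col]]))
        df[[col]] <- c(G_unit = "kcal/mol", state_tag = "1M",
                       multiplicity = "1")[[col]]
    df$multiplicity <- as.integer(df$multiplicity)
    return(validate_species_table(df))
  }
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) {
    warning(sprintf("empty species table: %s", path))
    return(empty_species_table())
  }
  sep <- if (grepl("\t", raw[1])) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  missing <- setdiff(.species_cols, names(df))
  if (length(missing))
    rk_error(sprintf("species table %s is missing column(s): %s", path,
                     paste(missing, collapse = ", ")), "radkin_schema_error")
  G_num <- suppressWarnings(as.numeric(df$G))
  if (anyNA(G_num))
    rk_error(sprintf("unparseable energy '%s' in %s (line %d)",
                     df$G[is.na(G_num)][1], path, which(is.na(G_num))[1] + 1L),
             "radkin_parse_error")
  df$G <- G_num
  validate_species_table(df)
}

empty_species_table <- function() {
  df <- data.frame(label = character(), charge = integer(),
                   protonation_index = integer(), solvent = character(),
                   G = numeric(), G_unit = character(), state_tag = character(),
                   multiplicity = integer(), stringsAsFactors = FALSE)
  class(df) <- c("radkin_species", "data.frame")
  df
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write species or channel tables as tab-delimited text
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces the in-memory doubles exactly, and
#' re-running an unchanged generator yields byte-identical files.
#'
#' @param df a `radkin_species` or `radkin_channels` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(df, path) {
  out <- df
  out$G <- fmt_num(df$G)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a reaction-channel table
#'
#' One row per elementary scavenging path: the mechanism (FHT, a formal
#' hydrogen transfer from an O-H site, or SET, a single electron transfer),
#' the site label, the solvent, the reacting acid-base state, the reaction
#' free energy, and -- for FHT -- the activation free energy, the magnitude
#' of the transition state's imaginary frequency and the reaction-path
#' symmetry number. Channels that do not exist for a species (a deprotonated
#' site, SET in a lipid) are encoded explicitly with `present = FALSE` and
#' carry no energetic fields; they are excluded from every screening and sum.
#'
#' @param mechanism "FHT" or "SET".
#' @param site site label ("1", "2", ..., or "SET").
#' @param solvent solvent identifier.
#' @param species_label label of the reacting acid-base state.
#' @param dG_reaction reaction Gibbs energy, kcal/mol.
#' @param dG_activation activation Gibbs energy, kcal/mol (NA for SET until
#'   the Marcus step fills it).
#' @param imaginary_frequency magnitude, cm^-1 (NA for SET).
#' @param symmetry_number positive integer reaction-path degeneracy.
#' @param present logical; FALSE marks a non-existent channel.
#' @return a `data.frame` of class `radkin_channels`.
#' @export
channel_table <- function(mechanism, site, solvent, species_label,
                          dG_reaction = NA_real_, dG_activation = NA_real_,
                          imaginary_frequency = NA_real_,
                          symmetry_number = 1L, present = TRUE) {
  n <- max(length(mechanism), length(site), length(solvent),
           length(species_label))
  for (len in c(length(dG_reaction), length(dG_activation),
                length(imaginary_frequency), length(symmetry_number),
                length(present)))
    if (len > 1) n <- max(n, len)
  df <- data.frame(mechanism = rep_len(as.character(mechanism), n),
                   site = rep_len(as.character(site), n),
                   solvent = rep_len(as.character(solvent), n),
                   species_label = rep_len(as.character(species_label), n),
                   dG_reaction = rep_len(as.numeric(dG_reaction), n),
                   dG_activation = rep_len(as.numeric(dG_activation), n),
                   imaginary_frequency = rep_len(as.numeric(imaginary_frequency), n),
                   symmetry_number = rep_len(as.integer(symmetry_number), n),
                   present = rep_len(as.logical(present), n),
                   stringsAsFactors = FALSE)
  validate_channel_table(df)
}

validate_channel_table <- function(df, tol = 1e-6) {
  missing <- setdiff(.channel_cols, names(df))
  if (length(missing))
    rk_error(sprintf("channel table is missing column(s): %s",
                     paste(missing, collapse = ", ")), "radkin_schema_error")
  if (any(!df$mechanism %in% c("FHT", "SET")))
    rk_error("mechanism must be 'FHT' or 'SET'", "radkin_schema_error")
  if (any(df$symmetry_number[df$present] < 1L, na.rm = TRUE))
    rk_error("symmetry_number must be >= 1", "radkin_validation_error")
  # absent channels carry no energetics
  ab <- !df$present
  if (any(ab & (!is.na(df$dG_reaction) | !is.na(df$dG_activation) |
                  !is.na(df$imaginary_frequency))))
    rk_error("a channel marked present = FALSE must carry no energetic fields",
             "radkin_validation_error")
  fht <- df$present & df$mechanism == "FHT"
  bad_nu <- fht & !is.na(df$imaginary_frequency) & df$imaginary_frequency <= 0
  if (any(bad_nu))
    rk_error("imaginary_frequency must be > 0 when present",
             "radkin_validation_error")
  if (any(df$present & df$mechanism == "SET" & !is.na(df$imaginary_frequency)))
    rk_error("SET channels carry no imaginary frequency",
             "radkin_validation_error")
  # a transition state cannot lie below both endpoints
  has_act <- df$present & !is.na(df$dG_activation) & !is.na(df$dG_reaction)
  low <- has_act &
    df$dG_activation < pmax(0, df$dG_reaction) - tol
  if (any(low))
    rk_error(sprintf(
      "channel %s/%s site %s: dG_activation (%.3f) below max(0, dG_reaction) (%.3f)",
      df$species_label[low][1], df$mechanism[low][1], df$site[low][1],
      df$dG_activation[low][1], pmax(0, df$dG_reaction)[low][1]),
      "radkin_validation_error")
  class(df) <- c("radkin_channels", "data.frame")
  df
}

#' Read a reaction-channel table from delimited text
#'
#' Tab- or comma-delimited with a header row carrying the fixed column names
#' `mechanism, site, solvent, species_label, dG_reaction, dG_activation,
#' imaginary_frequency, symmetry_number, present`. Empty cells or "-"/"NA"
#' denote absent values; `present` is TRUE/FALSE.
#'
#' @param path file path.
#' @return a `radkin_channels` data.frame.
#' @export
read_channel_table <- function(path) {
  if (!file.exists(path))
    rk_error(sprintf("file not found: %s", path), "radkin_io_error")
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) {
    warning(sprintf("empty channel table: %s", path))
    return(validate_channel_table(channel_table(character(), character(),
                                                character(), character())))
  }
  sep <- if (grepl("\t", raw[1])) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", "", "-", "—"))
  missing <- setdiff(.channel_cols, names(df))
  if (length(missing))
    rk_error(sprintf("channel table %s is missing column(s): %s", path,
                     paste(missing, collapse = ", ")), "radkin_schema_error")
  for (col in c("dG_reaction", "dG_activation", "imaginary_frequency")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    unparsed <- !is.na(df[[col]]) & is.na(v)
    if (any(unparsed))
      rk_error(sprintf("unparseable value '%s' in column %s of %s (line %d)",
                       df[[col]][unparsed][1], col, path,
                       which(unparsed)[1] + 1L), "radkin_parse_error")
    df[[col]] <- v
  }
  df$symmetry_number <- as.integer(df$symmetry_number)
  df$present <- as.logical(df$present)
  validate_channel_table(df)
}

#' @rdname write_species_table
#' @export
write_channel_table <- function(df, path) {
  out <- df
  for (col in c("dG_reaction", "dG_activation", "imaginary_frequency"))
    out[[col]] <- fmt_num(df[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define a solvent environment
#'
#' @param name solvent identifier.
#' @param viscosity dynamic viscosity, Pa s.
#' @param temperature temperature, K.
#' @param polarity_class "aqueous" or "lipid".
#' @param pH the pH of the medium; required for aqueous solvents and
#'   disallowed for lipids (no acid-base speciation in a non-polar phase).
#' @return a list of class `radkin_solvent`.
#' @export
#' @examples
#' solvent_environment("water", 8.91e-4, 298.15, "aqueous", pH = 7.4)
solvent_environment <- function(name, viscosity, temperature = 298.15,
                                polarity_class = c("aqueous", "lipid"),
                                pH = NULL) {
  polarity_class <- match.arg(polarity_class)
  if (!is.numeric(viscosity) || viscosity <= 0)
    rk_error("viscosity must be > 0", "radkin_validation_error")
  if (!is.numeric(temperature) || temperature <= 0)
    rk_error("temperature must be > 0", "radkin_validation_error")
  if (polarity_class == "aqueous" && is.null(pH))
    rk_error("aqueous solvents require a pH", "radkin_validation_error")
  if (polarity_class == "lipid" && !is.null(pH))
    rk_error("pH is defined only for aqueous solvents", "radkin_validation_error")
  structure(list(name = name, viscosity = viscosity,
                 temperature = temperature, polarity_class = polarity_class,
                 pH = pH),
            class = "radkin_solvent")
}

#' Extract the thermal free energy from quantum-chemistry output text
#'
#' Scans plain text for the standard thermochemistry summary line
#' `Sum of electronic and thermal Free Energies=` and returns the value.
#' Exactly one such line must be present. Only this one dialect is
#' supported; any other output must be pre-tabulated by the user. The value
#' is returned in hartree at the 1 atm gas-phase standard state, which is
#' what frequency codes print (see [standard_state_correction()] for the
#' shift to 1 M).
#'
#' @param text character vector of lines, or one string with embedded
#'   newlines.
#' @return a list with `value` (hartree), `unit` ("hartree") and
#'   `state_tag` ("1atm").
#' @export
extract_thermochem_summary <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  pat <- "Sum of electronic and thermal Free Energies=\\s*(-?[0-9]*\\.?[0-9]+)"
  hits <- regmatches(lines, regexpr(pat, lines))
  if (length(hits) != 1L)
    rk_error(sprintf(
      "expected exactly one thermal-free-energy summary line, found %d",
      length(hits)), "radkin_extraction_error")
  value <- as.numeric(sub(pat, "\\1", hits))
  list(value = value, unit = "hartree", state_tag = "1atm")
}
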