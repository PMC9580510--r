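test_that("unit and standard-state conversions are lossless and invertible", {
  x <- c(-650.123456789, -0.5, 0, 123.456)
  expect_equal(kcal_to_hartree(hartree_to_kcal(x)), x, tolerance = 1e-10)
  expect_identical(hartree_to_kcal(1), 627.5095)
  dG <- c(-3.2, 0, 14.7)
  shifted <- standard_state_correction(dG, 298.15, molecularity_change = -1)
  back <- standard_state_correction(shifted, 298.15, molecularity_change = 1)
  expect_equal(back, dG, tolerance = 1e-12)
  # the bimolecular shift at 298.15 K is RT ln(24.46)
  expect_equal(dG - shifted, rep(.oRk * 298.15 * log(24.46), 3),
               tolerance = 1e-12)
})

test_that("species tables normalize units, reject duplicates, round-trip", {
  sp <- species_table(
    label = c("H3W", "H2W-", "HW2-", "W3-"),
    charge = 0:-3, protonation_index = 0:3, solvent = "water",
    G = c(-650.1, -649.6, -649.0, -648.2), G_unit = "hartree",
    state_tag = "1atm")
  expect_s3_class(sp, "radkin_species")
  expect_equal(sp$G, c(-650.1, -649.6, -649.0, -648.2) * 627.5095)
  expect_true(all(sp$G_unit == "kcal/mol"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_species_table(sp, path)
  back <- read_species_table(path)
  expect_identical(back$G, sp$G)     # exact double round trip
  expect_identical(back$label, sp$label)

  expect_error(species_table(c("H3W", "H3W"), 0, 0, "water", c(-1, -2)),
               regexp = "duplicate", class = "radkin_schema_error")
})

test_that("delimited readers flag schema and parse errors precisely", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tcharge\tsolvent", "H3W\t0\twater"), path)
  expect_error(read_species_table(path), regexp = "protonation_index",
               class = "radkin_schema_error")

  writeLines(paste(c("label\tcharge\tprotonation_index\tsolvent\tG\tG_unit\tstate_tag\tmultiplicity",
                     "H3W\t0\t0\twater\tnot-a-number\thartree\t1atm\t1"),
                   collapse = "\n"), path)
  err <- tryCatch(read_species_table(path), error = identity)
  expect_s3_class(err, "radkin_parse_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(character(0), path)
  expect_warning(out <- read_species_table(path), "empty")
  expect_equal(nrow(out), 0)
})

test_that("channel invariants: TS above endpoints, absent rows are inert", {
  expect_error(
    channel_table("FHT", "1", "water", "H3W", dG_reaction = 2,
                  dG_activation = 1, imaginary_frequency = 1200),
    regexp = "below", class = "radkin_validation_error")
  # barely-above TS within tolerance is accepted
  ok <- channel_table("FHT", "1", "water", "H3W", dG_reaction = -5,
                      dG_activation = 0, imaginary_frequency = 1200)
  expect_s3_class(ok, "radkin_channels")
  expect_error(
    channel_table("FHT", "2", "water", "H2W-", dG_reaction = -1,
                  dG_activation = 5, imaginary_frequency = 1000,
                  present = FALSE),
    regexp = "no energetic fields", class = "radkin_validation_error")
  expect_error(
    channel_table("SET", "SET", "water", "H3W", dG_reaction = 5,
                  imaginary_frequency = 900),
    regexp = "imaginary", class = "radkin_validation_error")
})

test_that("channel tables round-trip through disk including absent cells", {
  ch <- channel_table(
    mechanism = c("FHT", "FHT", "SET"), site = c("1", "2", "SET"),
    solvent = "water", species_label = c("H3W", "H2W-", "H3W"),
    dG_reaction = c(-0.82, NA, 33.61),
    dG_activation = c(12.3456789012345, NA, NA),
    imaginary_frequency = c(1517.2, NA, NA),
    symmetry_number = 1L, present = c(TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_channel_table(ch, path)
  back <- read_channel_table(path)
  expect_identical(back$dG_activation, ch$dG_activation)
  expect_identical(back$present, ch$present)
})

test_that("thermochemistry extraction accepts exactly one summary line", {
  txt <- c("SCF Done: E(RM062X) = -650.9",
           " Sum of electronic and thermal Free Energies=   -100.123456",
           "trailing")
  out <- extract_thermochem_summary(txt)
  expect_equal(out$value, -100.123456)
  expect_identical(out$unit, "hartree")
  expect_identical(out$state_tag, "1atm")

  err0 <- tryCatch(extract_thermochem_summary("no such line"),
                   error = identity)
  expect_s3_class(err0, "radkin_extraction_error")
  expect_match(conditionMessage(err0), "found 0")
  err2 <- tryCatch(extract_thermochem_summary(rep(txt[2], 2)),
                   error = identity)
  expect_match(conditionMessage(err2), "found 2")
})

test_that("solvent environments enforce the pH/polarity pairing", {
  expect_error(solvent_environment("water", 8.91e-4, 298.15, "aqueous"),
               regexp = "pH", class = "radkin_validation_error")
  expect_error(solvent_environment("pentyl ethanoate", 8.62e-4, 298.15,
                                   "lipid", pH = 7.4),
               class = "radkin_validation_error")
  expect_error(solvent_environment("water", -1, 298.15, "aqueous", pH = 7),
               class = "radkin_validation_error")
})
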