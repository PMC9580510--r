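test_that("fixture specs validate their ranges and demand a seed", {
  expect_error(fixture_spec(), class = "radkin_validation_error")
  expect_error(fixture_spec(pka_targets = c(9, 5, 12), seed = 1),
               regexp = "increasing", class = "radkin_validation_error")
  expect_error(fixture_spec(barrier_range = c(18, 5), seed = 1),
               class = "radkin_validation_error")
  expect_error(fixture_spec(barrier_range = c(0.5, 2), seed = 1),
               regexp = "barrier_range", class = "radkin_validation_error")
})

test_that("the same seed yields byte-identical fixture files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 42), dir = d1)
  generate_fixture(fixture_spec(seed = 42), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 43), dir = d3)
  expect_false(identical(readLines(file.path(d1, "channels.tsv")),
                         readLines(file.path(d3, "channels.tsv"))))
})

test_that("fixture tables re-read through the standard readers", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(seed = 7), dir = d)
  sp <- read_species_table(file.path(d, "species.tsv"))
  ch <- read_channel_table(file.path(d, "channels.tsv"))
  expect_identical(sp$G, fx$species$G)
  expect_identical(ch$dG_activation, fx$channels$dG_activation)
  expect_identical(ch$present, fx$channels$present)
  hdr <- yaml::read_yaml(file.path(d, "fixture.yaml"))
  expect_identical(hdr$seed, 7L)
})

test_that("the isodesmic inputs invert back to the target pKa values", {
  fx <- generate_fixture(fixture_spec(seed = 42))
  pkas <- pka_isodesmic(fx$isodesmic$dG_exchange,
                        fx$isodesmic$pka_reference)
  expect_equal(pkas, fx$spec$pka_targets, tolerance = 1e-12)
})

test_that("exactly the constructed endergonic channels hit the screen", {
  fx <- generate_fixture(fixture_spec(seed = 42))
  scr <- screen_exergonic(fx$channels)
  gt <- fx$ground_truth$endergonic_channels
  expect_equal(nrow(scr$omitted), nrow(gt))
  expect_setequal(paste(scr$omitted$mechanism, scr$omitted$site,
                        scr$omitted$solvent, scr$omitted$species_label),
                  paste(gt$mechanism, gt$site, gt$solvent, gt$species_label))
  # the forced lipid endergonic channel is among them
  expect_true(any(scr$omitted$solvent == "pentyl ethanoate" &
                    scr$omitted$site == "1"))
})

test_that("inverting the Eyring step recovers the drawn barriers", {
  fx <- generate_fixture(fixture_spec(seed = 42))
  gt <- fx$ground_truth$per_channel
  key <- paste(fx$channels$mechanism, fx$channels$site, fx$channels$solvent,
               fx$channels$species_label)
  drawn <- fx$channels$dG_activation[
    match(paste(gt$mechanism, gt$site, gt$solvent, gt$species_label), key)]
  back <- dG_activation_from_rate(gt$k_tst, fx$spec$temperature,
                                  symmetry_number = 1,
                                  tunneling_factor = gt$kappa)
  expect_equal(back, drawn, tolerance = 1e-8)
})

test_that("a degenerate barrier range equalizes same-sigma channel rates", {
  sp <- fixture_spec(barrier_range = c(12, 12), seed = 5)
  fx <- generate_fixture(sp)
  rep <- run_pipeline(fixture_config(fx))
  # within one species and solvent the only per-channel differences are the
  # tunneling factors; with one shared barrier, Gamma varies only through
  # kappa, and k_tst / kappa is constant
  rt <- rep$rates
  for (key in split(seq_len(nrow(rt)),
                    paste(rt$species_label, rt$solvent))) {
    base <- rt$k_tst[key] / rt$kappa[key]
    expect_lt(diff(range(base)) / base[1], 1e-12)
  }
})

test_that("full-pipeline round trip reproduces the fixture ground truth", {
  fx <- generate_fixture(fixture_spec(seed = 42))
  rep <- run_pipeline(fixture_config(fx))
  gt <- fx$ground_truth
  expect_equal(rep$k_overall[["water"]], gt$k_overall_aqueous,
               tolerance = 1e-10)
  expect_equal(rep$k_overall[["pentyl ethanoate"]], gt$k_overall_lipid,
               tolerance = 1e-10)
  expect_equal(rep$k_total[names(gt$k_total)], gt$k_total,
               tolerance = 1e-10)
  for (key in names(gt$gamma)) {
    got <- rep$gamma[[key]][names(gt$gamma[[key]])]
    expect_lt(max(abs(got - gt$gamma[[key]])), 1e-9)
  }
  expect_equal(as.numeric(rep$speciation$fractions),
               as.numeric(gt$fractions), tolerance = 1e-12)
})
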