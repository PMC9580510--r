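# Channel grid of a triprotic gallate-bearing phenol (H3W) and its first
# anion (H2W-) reacting with HOO., as tabulated reaction free energies:
# used across the screening tests.
wal_channels <- function() {
  channel_table(
    mechanism = c(rep("FHT", 3), "SET", rep("FHT", 3), "SET",
                  rep("FHT", 3), "SET"),
    site = rep(c("1", "2", "3", "SET"), 3),
    solvent = c(rep("water", 8), rep("pentyl ethanoate", 4)),
    species_label = c(rep("H3W", 4), rep("H2W-", 4), rep("H3W", 4)),
    dG_reaction = c(-0.82, -6.14, -1.47, 33.61,
                    -13.46, NA, -12.56, 5.25,
                    0.63, -5.43, -0.06, NA),
    present = c(rep(TRUE, 5), FALSE, rep(TRUE, 5), FALSE))
}

test_that("exergonicity screening removes exactly the endergonic channels", {
  scr <- screen_exergonic(wal_channels())
  # one lipid FHT channel (site 1, +0.63) and both aqueous SET channels go
  expect_equal(nrow(scr$omitted), 3)
  om <- scr$omitted
  expect_setequal(paste(om$mechanism, om$site, om$solvent),
                  c("FHT 1 pentyl ethanoate", "SET SET water",
                    "SET SET water"))
  expect_setequal(om$dG_reaction, c(0.63, 33.61, 5.25))
  # every aqueous FHT channel of both species survives
  ret <- scr$retained
  aq_fht <- ret[ret$solvent == "water" & ret$mechanism == "FHT", ]
  expect_equal(nrow(aq_fht), 5)
  # the anion's deprotonated site was never a channel at all
  expect_false(any(scr$report$species_label == "H2W-" &
                     scr$report$site == "2" &
                     scr$report$decision != "absent"))
})

test_that("screening keeps the dG = 0 boundary and validates inputs", {
  ch <- channel_table("FHT", c("1", "2"), "water", "X",
                      dG_reaction = c(0, 1e-9),
                      dG_activation = c(8, 8),
                      imaginary_frequency = 1000)
  scr <- screen_exergonic(ch)
  expect_equal(scr$retained$site, "1")   # 0 retained, strictly positive cut
  expect_equal(scr$omitted$site, "2")
  bad <- channel_table("FHT", "1", "water", "X")
  expect_error(screen_exergonic(bad), regexp = "dG_reaction",
               class = "radkin_validation_error")
})

test_that("k_total is a plain sum with a warned empty case", {
  expect_identical(k_total(5e3), 5e3)
  expect_identical(k_total(c(1e4, 2e4, 3e4)), 6e4)
  expect_warning(z <- k_total(numeric(0)), regexp = "k_total = 0")
  expect_identical(z, 0)
})

test_that("fraction weighting reproduces the published aggregation", {
  agg <- k_overall_at_pH(c(H3W = 1.99e4, `H2W-` = 1.35e8),
                         c(H3W = 0.942, `H2W-` = 0.058))
  expect_equal(signif(agg$k_f[["H3W"]], 3), 1.87e4)
  expect_equal(signif(agg$k_f[["H2W-"]], 3), 7.83e6)
  expect_equal(signif(agg$k_overall, 3), 7.85e6)
})

test_that("fraction weighting degenerates, warns and bounds correctly", {
  # single species at f = 1: overall equals total (the lipid-phase case)
  one <- k_overall_at_pH(c(H3W = 4.84e5), c(H3W = 1))
  expect_identical(one$k_overall, 4.84e5)
  expect_equal(k_overall_at_pH(c(a = 2, b = 4),
                               c(a = 0.5, b = 0.5))$k_overall, 3)
  expect_warning(
    out <- k_overall_at_pH(c(a = 10, b = 20), c(a = 0.6)),
    regexp = "f = 0")
  expect_identical(out$k_f[["b"]], 0)
  expect_error(k_overall_at_pH(c(a = 1), c(a = -0.1)),
               class = "radkin_validation_error")
  # weighted mean bound
  set.seed(3)
  for (i in 1:50) {
    kt <- setNames(10^runif(3, 2, 9), c("a", "b", "c"))
    f <- runif(3); f <- setNames(f / sum(f), names(kt))
    ko <- k_overall_at_pH(kt, f)$k_overall
    expect_gte(ko + 1e-12, min(kt) * sum(f))
    expect_lte(ko - 1e-12, max(kt) * sum(f))
  }
})

test_that("branching ratios are percentages that always close to 100", {
  expect_identical(branching_ratios(7), 100)
  expect_identical(as.numeric(branching_ratios(c(1, 1))), c(50, 50))
  # published-style proportions pass through unchanged
  g <- branching_ratios(c(s2 = 99.15, s1 = 0.27, s3 = 0.58))
  expect_equal(as.numeric(g), c(99.15, 0.27, 0.58), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:1000) {
    k <- 10^runif(sample(2:6, 1), 0, 9)
    expect_lt(abs(sum(branching_ratios(k)) - 100), 1e-9)
  }
  expect_error(branching_ratios(c(0, 0)), class = "radkin_validation_error")
})

test_that("removing a channel renormalizes branching consistently", {
  k <- c(a = 5e4, b = 3e6, c = 2e5)
  g_full <- branching_ratios(k)
  g_drop <- branching_ratios(k[-1])
  expect_equal(as.numeric(g_drop), as.numeric(100 * k[-1] / sum(k[-1])),
               tolerance = 1e-12)
  expect_gt(g_drop[["b"]], g_full[["b"]])
})

test_that("aggregation is invariant under channel and species ordering", {
  set.seed(21)
  kt <- setNames(10^runif(4, 3, 8), letters[1:4])
  f <- setNames(as.numeric(molar_fractions(c(6, 8, 10), 7.4)$fractions),
                letters[1:4])
  a <- k_overall_at_pH(kt, f)$k_overall
  p <- sample(4)
  b <- k_overall_at_pH(kt[p], f[p])$k_overall
  expect_equal(a, b, tolerance = 1e-15)
})

test_that("reference comparisons reproduce published fold-changes", {
  lipid <- 4.84e5
  expect_identical(compare_to_reference(lipid, 9.70e4, "Trolox")$fold_rounded,
                   5)
  expect_identical(
    compare_to_reference(lipid, 7.80e4, "ascorbic acid")$fold_rounded, 6)
  expect_equal(compare_to_reference(lipid, 9.70e4)$fold, 4.98969,
               tolerance = 1e-5)
  expect_identical(compare_to_reference(3, 3)$fold, 1)
  expect_error(compare_to_reference(1, 0), class = "radkin_validation_error")
})
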