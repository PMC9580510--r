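test_that("Eyring prefactor and exponential scaling match the closed form", {
  # kB T / h at 298.15 K from the defining constants
  pref <- .okB * 298.15 / .oh
  expect_equal(pref, 6.212438e12, tolerance = 1e-6)
  expect_equal(eyring_rate(0), pref, tolerance = 1e-12)
  # a barrier of 10 RT ln10 costs exactly ten decades
  expect_equal(eyring_rate(10 * .oRk * 298.15 * log(10)), pref * 1e-10,
               tolerance = 1e-10)
  # linear in kappa and sigma
  expect_equal(eyring_rate(5, tunneling_factor = 2), 2 * eyring_rate(5))
  expect_equal(eyring_rate(5, symmetry_number = 2), 2 * eyring_rate(5))
  expect_error(eyring_rate(5, tunneling_factor = -1),
               class = "radkin_validation_error")
})

test_that("Eyring inversion recovers the barrier to 1e-10 kcal/mol", {
  dG <- c(0.3, 7.77, 13.642, 21.5)
  k <- eyring_rate(dG, 310, symmetry_number = 3, tunneling_factor = 2.5)
  back <- dG_activation_from_rate(k, 310, symmetry_number = 3,
                                  tunneling_factor = 2.5)
  expect_equal(back, dG, tolerance = 1e-10)
})

test_that("rates fall with barrier height and rise with temperature", {
  dG <- seq(0, 20, by = 0.5)
  expect_true(all(diff(eyring_rate(dG)) < 0))
  Tt <- seq(250, 400, by = 10)
  expect_true(all(diff(eyring_rate(8, Tt)) > 0))
})

test_that("Wigner correction matches its closed form and is monotone", {
  expect_identical(wigner_tunneling(0), 1)
  expect_equal(wigner_tunneling(1000), wigner_oracle(1000, 298.15),
               tolerance = 1e-12)
  expect_equal(wigner_tunneling(1000), 1.97030, tolerance = 1e-5)
  nu <- seq(0, 3000, by = 100)
  expect_true(all(diff(wigner_tunneling(nu)) > 0))
})

test_that("Eckart correction obeys its physical limits", {
  # vanishing curvature: no tunneling enhancement
  expect_equal(eckart_tunneling(1e-3, 5, 10), 1, tolerance = 1e-4)
  # classical (high temperature) limit
  expect_equal(eckart_tunneling(1500, 5, 10, temperature = 1e4), 1,
               tolerance = 0.01)
  # always an enhancement
  set.seed(7)
  for (i in 1:20) {
    kap <- eckart_tunneling(runif(1, 300, 2500), runif(1, 1, 12),
                            runif(1, 1, 14))
    expect_gte(kap, 1)
  }
})

test_that("Eckart agrees with a fine-grid trapezoid quadrature oracle", {
  kap <- eckart_tunneling(1500, 5, 10)
  ora <- eckart_kappa_oracle(1500, 5, 10, 298.15)
  expect_equal(kap, ora, tolerance = 5e-4)  # 3 significant figures
})

test_that("Eckart approaches Wigner for gentle barrier curvature", {
  # low imaginary frequency and moderate barriers: the parabolic expansion
  # the Wigner factor is built on is accurate there
  set.seed(11)
  for (i in 1:10) {
    nu <- runif(1, 100, 300)
    V1 <- runif(1, 2, 5)
    V2 <- V1 + runif(1, 0, 3)
    eck <- eckart_tunneling(nu, V1, V2)
    wig <- wigner_tunneling(nu)
    expect_lt(abs(eck / wig - 1), 0.05)
  }
})
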