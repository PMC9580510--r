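# Independent oracles used across the suite. These deliberately re-derive
# each quantity by a different route than the package (linear-system
# equilibrium solve, fixed-grid trapezoid quadrature, single-expression
# arithmetic) so agreement is a two-sided check.

# CODATA 2018 defining constants, bound locally for the oracles
.okB <- 1.380649e-23
.oh <- 6.62607015e-34
.oNA <- 6.02214076e23
.oc <- 2.99792458e10
.oRk <- .okB * .oNA / 4184

# Brute-force polyprotic speciation: solve the mass-action linear system
# Ka_i * x_{i-1} = [H+] * x_i, sum(x) = 1, with base::solve().
mass_action_fractions <- function(pkas, pH) {
  n <- length(pkas)
  H <- 10^(-pH)
  Ka <- 10^(-pkas)
  A <- matrix(0, n + 1, n + 1)
  b <- c(rep(0, n), 1)
  for (i in seq_len(n)) {
    A[i, i] <- Ka[i]
    A[i, i + 1] <- -H
  }
  A[n + 1, ] <- 1
  # scale equilibrium rows to unit norm so extreme Ka values stay well
  # conditioned under partial pivoting
  for (i in seq_len(n)) {
    s <- max(abs(A[i, ]))
    A[i, ] <- A[i, ] / s
  }
  as.numeric(solve(A, b))
}

# Eckart transmission probability, plain direct arithmetic (valid for the
# moderate barriers used in tests, where cosh() cannot overflow)
eckart_P_oracle <- function(E, V1, V2, hnu) {
  a1 <- 2 * pi * V1 / hnu
  a2 <- 2 * pi * V2 / hnu
  denom <- 1 / sqrt(a1) + 1 / sqrt(a2)
  xi <- E / V1
  a <- 2 * sqrt(a1 * xi) / denom
  b <- 2 * sqrt(pmax(a1 * xi - a1 + a2, 0)) / denom  # clamp E0 rounding
  d2 <- a1 * a2 - pi^2 / 4
  cd <- if (d2 >= 0) cosh(2 * sqrt(d2)) else cos(2 * sqrt(-d2))
  1 - (cosh(a - b) + cd) / (cosh(a + b) + cd)
}

# Boltzmann average by fine-grid trapezoid quadrature
eckart_kappa_oracle <- function(nu_cm, V1_kcal, V2_kcal, temperature,
                                n_grid = 40001L) {
  kT <- .okB * temperature
  hnu <- .oh * .oc * nu_cm
  V1 <- V1_kcal * 4184 / .oNA
  V2 <- V2_kcal * 4184 / .oNA
  E0 <- max(0, V1 - V2)
  E <- seq(E0, V1 + 45 * kT, length.out = n_grid)
  g <- eckart_P_oracle(E, V1, V2, hnu) * exp((V1 - E) / kT)
  g[1] <- 0  # P(E0) = 0 at the asymptote
  h <- E[2] - E[1]
  (h * (sum(g) - (g[1] + g[n_grid]) / 2)) / kT
}

# Single-expression diffusion chain: Stokes-Einstein for both partners,
# Smoluchowski at the encounter distance, Collins-Kimball cap
diffusion_chain_oracle <- function(temperature, viscosity, rA, rB, Rab,
                                   k_act) {
  kD <- 4 * pi * Rab *
    (.okB * temperature / (6 * pi * viscosity) * (1 / rA + 1 / rB)) *
    .oNA * 1000
  k_act * kD / (k_act + kD)
}

# Wigner factor from first principles
wigner_oracle <- function(nu_cm, temperature) {
  1 + (.oh * .oc * nu_cm / (.okB * temperature))^2 / 24
}
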