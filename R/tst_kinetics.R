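#' Conventional transition-state-theory (Eyring) rate constant
#'
#' k = sigma * kappa * (kB T / h) * exp(-dG_activation / RT)
#'
#' at the 1 M / 298.15 K standard state conventionally used for solution
#' kinetics. For a bimolecular channel the 1 M standard state is assumed
#' already folded into `dG_activation` (see [standard_state_correction()]
#' for the shift from 1 atm thermochemistry), so the same expression yields
#' s^-1 for unimolecular and M^-1 s^-1 for bimolecular channels.
#'
#' @param dG_activation activation free energy, kcal/mol (vectorized).
#' @param temperature temperature, K.
#' @param symmetry_number reaction-path degeneracy sigma (>= 1).
#' @param tunneling_factor dimensionless transmission coefficient kappa
#'   (use 1 for none; see [eckart_tunneling()] and [wigner_tunneling()]).
#' @return rate constant(s), s^-1 or M^-1 s^-1 according to molecularity.
#' @export
#' @examples
#' eyring_rate(0)                         # kB T / h = 6.2124e12 s^-1
#' eyring_rate(13.6425)                   # ~1e-10 of the prefactor
eyring_rate <- function(dG_activation, temperature = 298.15,
                        symmetry_number = 1, tunneling_factor = 1) {
  if (any(temperature <= 0))
    rk_error("temperature must be > 0", "radkin_validation_error")
  if (any(symmetry_number < 1))
    rk_error("symmetry_number must be >= 1", "radkin_validation_error")
  if (any(tunneling_factor < 0))
    rk_error("tunneling_factor must be >= 0", "radkin_validation_error")
  symmetry_number * tunneling_factor * (.const$kB * temperature / .const$h) *
    exp(-dG_activation / (.const$R_kcal * temperature))
}

#' Invert the Eyring equation: activation free energy from a rate constant
#'
#' @param k rate constant, s^-1 or M^-1 s^-1.
#' @inheritParams eyring_rate
#' @return dG_activation in kcal/mol.
#' @export
dG_activation_from_rate <- function(k, temperature = 298.15,
                                    symmetry_number = 1, tunneling_factor = 1) {
  if (any(k <= 0)) rk_error("k must be > 0", "radkin_validation_error")
  -.const$R_kcal * temperature *
    log(k / (symmetry_number * tunneling_factor *
               .const$kB * temperature / .const$h))
}

#' Wigner tunneling correction
#'
#' The leading-order correction from the curvature of the barrier top:
#' kappa = 1 + (1/24) * (h c nu / kB T)^2, with nu the magnitude of the
#' transition state's imaginary wavenumber. Cheap and parameter-free, but it
#' underestimates deep tunneling through high thin barriers; used here as a
#' cross-check and fallback for the Eckart correction.
#'
#' @param imaginary_frequency magnitude of the imaginary wavenumber,
#'   cm^-1 (vectorized; >= 0).
#' @param temperature temperature, K.
#' @return dimensionless kappa >= 1.
#' @export
#' @examples
#' wigner_tunneling(1000)   # ~1.97 at 298.15 K
wigner_tunneling <- function(imaginary_frequency, temperature = 298.15) {
  if (any(imaginary_frequency < 0))
    rk_error("imaginary_frequency must be >= 0", "radkin_validation_error")
  u <- .const$h * .const$c_cm * imaginary_frequency /
    (.const$kB * temperature)
  1 + u^2 / 24
}

# log(cosh(z)) without overflow
.logcosh <- function(z) abs(z) + log1p(exp(-2 * abs(z))) - log(2)

# Transmission probability through the asymmetric Eckart barrier.
# E_J: energy above the reactant asymptote (J, per molecule); V1_J, V2_J:
# forward and reverse barrier heights (J); hnu: h * c * nu (J).
.eckart_transmission <- function(E_J, V1_J, V2_J, hnu) {
  alpha1 <- 2 * pi * V1_J / hnu
  alpha2 <- 2 * pi * V2_J / hnu
  inv <- 1 / sqrt(alpha1) + 1 / sqrt(alpha2)
  xi <- E_J / V1_J
  a <- 2 * sqrt(alpha1 * xi) / inv
  b2 <- alpha1 * xi - alpha1 + alpha2          # >= 0 for E above both asymptotes
  b <- 2 * sqrt(pmax(b2, 0)) / inv
  d2 <- alpha1 * alpha2 - pi^2 / 4
  P <- numeric(length(E_J))
  ok <- b2 >= 0 & E_J > 0
  if (!any(ok)) return(P)
  aa <- a[ok]; bb <- b[ok]
  if (d2 >= 0) {
    d <- 2 * sqrt(d2)
    # P = 1 - (cosh(a-b) + cosh(d)) / (cosh(a+b) + cosh(d)), in log space
    lnum <- .lse2(.logcosh(aa - bb), .logcosh(d))
    lden <- .lse2(.logcosh(aa + bb), .logcosh(d))
    P[ok] <- -expm1(lnum - lden)
  } else {
    # shallow barrier: d becomes imaginary, cosh(d) -> cos(|d|); arguments
    # are small in this regime so direct evaluation is safe
    cd <- cos(2 * sqrt(-d2))
    P[ok] <- 1 - (cosh(aa - bb) + cd) / (cosh(aa + bb) + cd)
  }
  pmin(pmax(P, 0), 1)
}

# Composite Simpson quadrature with interval doubling until the estimate
# changes by less than tol_rel * max(|I|, scale); deterministic and immune
# to the error-estimation heuristics of extrapolating adaptive rules.
.simpson_panel <- function(f, a, b, tol_rel, scale, n0 = 64L,
                           max_doublings = 16L) {
  if (b <= a) return(0)
  n <- n0
  prev <- NA_real_
  delta <- Inf
  for (it in seq_len(max_doublings)) {
    x <- seq(a, b, length.out = n + 1L)
    y <- f(x)
    h <- (b - a) / n
    I <- h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) +
                    2 * sum(y[seq(3, n - 1, 2)]))
    if (!is.na(prev)) {
      delta <- abs(I - prev)
      if (delta <= tol_rel * max(abs(I), scale)) return(I)
    }
    prev <- I
    n <- n * 2L
  }
  rk_error(sprintf(
    "Eckart quadrature did not converge (residual %.3e after %d refinements)",
    delta, max_doublings), "radkin_numerical_error")
}

.lse2 <- function(x, y) {
  m <- pmax(x, y)
  m + log(exp(x - m) + exp(y - m))
}

#' Eckart tunneling correction
#'
#' Boltzmann-averaged transmission probability through the asymmetric
#' one-dimensional Eckart barrier whose forward and reverse heights are the
#' activation free energies of the two directions and whose width is set by
#' the magnitude of the transition state's imaginary frequency:
#'
#'   kappa = exp(V1/kB T) / (kB T) * integral_{E0}^{inf} P(E) exp(-E/kB T) dE
#'
#' with E0 the higher of the two asymptotes and P(E) the exact Eckart
#' transmission probability. The Boltzmann average is evaluated after the
#' substitution u = exp(-(E - E0)/kB T), which absorbs the exponential
#' weight and maps the infinite energy range onto the bounded integral of
#' P over u in (0, 1] -- the raw energy-domain integrand spans tens of
#' orders of magnitude and defeats adaptive quadrature error estimates.
#' The u integral is split at the above-barrier point and evaluated
#' adaptively under a purely relative tolerance (default 1e-8).
#'
#' @param imaginary_frequency magnitude of the imaginary wavenumber, cm^-1
#'   (> 0).
#' @param dG_forward forward barrier height, kcal/mol (> 0).
#' @param dG_reverse reverse barrier height, kcal/mol (> 0).
#' @param temperature temperature, K.
#' @param rel_tol relative tolerance of the quadrature.
#' @return dimensionless kappa >= 1 (vectorized over the first three
#'   arguments).
#' @export
#' @examples
#' eckart_tunneling(1500, 5, 10)   # H-transfer-like barrier at 298.15 K
eckart_tunneling <- function(imaginary_frequency, dG_forward, dG_reverse,
                             temperature = 298.15, rel_tol = 1e-8) {
  n <- max(length(imaginary_frequency), length(dG_forward), length(dG_reverse))
  nu <- rep_len(imaginary_frequency, n)
  V1 <- rep_len(dG_forward, n)
  V2 <- rep_len(dG_reverse, n)
  if (any(nu <= 0))
    rk_error("imaginary_frequency must be > 0", "radkin_validation_error")
  if (any(V1 <= 0) || any(V2 <= 0))
    rk_error("barrier heights must be > 0", "radkin_validation_error")
  if (temperature <= 0)
    rk_error("temperature must be > 0", "radkin_validation_error")
  kT <- .const$kB * temperature
  vapply(seq_len(n), function(i) {
    hnu <- .const$h * .const$c_cm * nu[i]
    # vanishing barrier curvature: the transmission approaches a classical
    # step whose boundary layer no quadrature grid can resolve, and the
    # Boltzmann average reduces analytically to the Wigner expansion
    if (hnu < 0.05 * kT)
      return(1 + (hnu / kT)^2 / 24)
    V1J <- V1[i] * 4184 / .const$`NA`
    V2J <- V2[i] * 4184 / .const$`NA`
    E0 <- max(0, V1J - V2J)
    # substitute E = E0 + kT s^2: the Eckart wave numbers are analytic in s
    # at the lower endpoint (no sqrt-in-energy kink) and the Boltzmann
    # weight becomes a Gaussian, so the integrand is smooth and compact:
    #   kappa = e^{(V1-E0)/kT} * int_0^inf P(E0 + kT s^2) e^{-s^2} 2s ds
    f <- function(s) .eckart_transmission(E0 + kT * s^2, V1J, V2J, hnu) *
      exp(-s^2) * 2 * s
    # kappa >= 1 bounds the integral from below by e^{-(V1-E0)/kT}, giving
    # the absolute floor of the convergence tolerance
    scale <- exp(-(V1J - E0) / kT)
    I <- .simpson_panel(f, 0, sqrt(40), rel_tol, scale)
    exp((V1J - E0) / kT) * I
  }, numeric(1))
}
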