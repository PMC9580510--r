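#' Isodesmic pKa from a proton-exchange reaction free energy
#'
#' The pKa of a target acid HA is referenced to a structurally similar acid
#' HRef of known pKa through the proton-exchange (isodesmic) reaction
#' HA + Ref- -> A- + HRef, whose solution free energy dG_exchange carries
#' the acidity difference:
#'
#'   pKa(HA) = pKa(HRef) + dG_exchange / (RT ln 10)
#'
#' Systematic solvation-model errors largely cancel between the two acids,
#' which is why the isodesmic route is preferred over absolute
#' thermochemical cycles.
#'
#' @param dG_exchange proton-exchange reaction free energy, kcal/mol
#'   (vectorized).
#' @param pka_reference pKa of the reference acid.
#' @param temperature temperature, K.
#' @return pKa values (dimensionless).
#' @export
#' @examples
#' pka_isodesmic(0, 4.75)               # 4.75: identical acidity
#' pka_isodesmic(1.36425, 4.75)         # one pKa unit above the reference
pka_isodesmic <- function(dG_exchange, pka_reference, temperature = 298.15) {
  if (any(temperature <= 0)) rk_error("temperature must be > 0",
                                      "radkin_validation_error")
  pka_reference + dG_exchange / (.const$R_kcal * temperature * log(10))
}

#' Invert the isodesmic relation: exchange free energy for a target pKa
#'
#' Used by the fixture generator to construct proton-exchange energies that
#' reproduce prescribed pKa values exactly.
#'
#' @inheritParams pka_isodesmic
#' @param pka target pKa.
#' @return dG_exchange in kcal/mol.
#' @export
dG_exchange_for_pka <- function(pka, pka_reference, temperature = 298.15) {
  (pka - pka_reference) * .const$R_kcal * temperature * log(10)
}

#' Molar fractions of the acid-base states of a polyprotic acid
#'
#' Generalized Henderson-Hasselbalch speciation: for an n-protic acid HnA
#' with macroscopic constants pKa_1 < ... < pKa_n, the fraction of the state
#' with i protons removed is
#'
#'   f_i = 10^(sum_{j<=i} (pH - pKa_j)) / sum_k 10^(sum_{j<=k} (pH - pKa_j))
#'
#' evaluated in log10 space so extreme pKa gaps cannot overflow. Activity
#' coefficients are ignored (ideal-dilute assumption). Fractions are exact
#' at the symmetric point: a monoprotic acid at pH = pKa returns
#' exactly (0.5, 0.5).
#'
#' @param pkas strictly increasing numeric vector of macroscopic pKa values
#'   (length 0-4 supported; length 0 yields the single fully protonated
#'   state with fraction 1).
#' @param pH the pH.
#' @return an object of class `speciation_profile`: a list with `pkas`,
#'   `pH`, and `fractions`, a numeric vector named by protonation index
#'   ("0" = fully protonated). Fractions sum to 1.
#' @export
#' @examples
#' molar_fractions(7.4, 7.4)                       # (0.5, 0.5)
#' molar_fractions(c(8.71, 14.59, 25.11), 7.4)     # triprotic phenol at pH 7.4
molar_fractions <- function(pkas, pH) {
  pkas <- as.numeric(pkas)
  if (length(pkas) > 4)
    rk_error("at most 4 acidic sites are supported", "radkin_validation_error")
  if (length(pkas) >= 2 && any(diff(pkas) <= 0))
    rk_error("pkas must be strictly increasing", "radkin_validation_error")
  if (!is.numeric(pH) || length(pH) != 1L || !is.finite(pH))
    rk_error("pH must be a single finite number", "radkin_validation_error")
  lg <- c(0, cumsum(pH - pkas))           # log10 of unnormalized fractions
  lg <- lg - max(lg)
  f <- 10^lg
  f <- f / sum(f)
  structure(list(pkas = pkas, pH = pH,
                 fractions = setNames(f, as.character(seq_along(f) - 1L))),
            class = "speciation_profile")
}

#' @export
print.speciation_profile <- function(x, ...) {
  cat(sprintf("Speciation at pH %.2f (pKa: %s)\n", x$pH,
              paste(format(x$pkas), collapse = ", ")))
  disp <- round(x$fractions, 3)
  for (i in seq_along(x$fractions))
    cat(sprintf("  state %s (protons removed): f = %.6g (display %.3f)\n",
                names(x$fractions)[i], x$fractions[i], disp[i]))
  invisible(x)
}

#' Speciation profile over a pH grid
#'
#' @inheritParams molar_fractions
#' @param pH_grid numeric vector of pH values (default 0-14 in steps
#'   of 0.1).
#' @return a data.frame with one row per pH and one `f_<i>` column per
#'   protonation state.
#' @export
speciation_grid <- function(pkas, pH_grid = seq(0, 14, by = 0.1)) {
  frac <- t(vapply(pH_grid, function(p) molar_fractions(pkas, p)$fractions,
                   numeric(length(pkas) + 1L)))
  out <- data.frame(pH = pH_grid, frac)
  names(out) <- c("pH", paste0("f_", seq_len(ncol(frac)) - 1L))
  out
}
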