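---
title: "Antiradical kinetics from solution thermochemistry"
author: "radkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antiradical kinetics from solution thermochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radkin)
```

# The problem

Phenolic antioxidants scavenge reactive oxygen species such as the
hydroperoxyl radical (HOO·) through several competing elementary channels:
formal hydrogen transfer (FHT) from each acidic O–H site, and single
electron transfer (SET) producing a radical cation (or a neutral radical
from an anion) plus HOO⁻. How fast a compound scavenges under physiological
conditions is not a property of one reaction: it is a fraction-weighted sum
over every acid–base state the compound populates at the ambient pH, summed
over every thermodynamically viable channel of each state, each corrected
for quantum tunneling and for the finite rate at which reactants diffuse
together.

`radkin` implements that composition. It starts from *tabulated* solution
thermochemistry — reaction free energies ΔG°, activation free energies
ΔG‡, transition-state imaginary frequencies, proton-exchange energies —
and produces the quantities kineticists report: pKa values, molar
fractions, per-channel rate constants, per-species totals $k_\mathrm{total}$,
fraction-corrected coefficients $k_f$, overall coefficients
$k_\mathrm{overall}$, and branching ratios $\Gamma$. The
electronic-structure calculations that produce those energies are outside
its scope by design: they belong to quantum-chemistry codes, and only a
single summary quantity (the thermal free energy line of a frequency
calculation) can be ingested directly via `extract_thermochem_summary()`.

# The model, stage by stage

## Isodesmic pKa and speciation

The pKa of each acidic site is referenced to a structurally similar acid of
known pKa through a proton-exchange reaction; systematic solvation-model
errors largely cancel, leaving

$$\mathrm{p}K_a = \mathrm{p}K_a^\mathrm{ref} + \frac{\Delta G_\mathrm{exch}}{RT\ln 10}.$$

`pka_isodesmic()` is that closed form; `dG_exchange_for_pka()` is its exact
inverse (used by the fixture generator).

Macroscopic speciation follows the generalized Henderson–Hasselbalch
relation: with strictly increasing $\mathrm{p}K_{a,1} < \dots <
\mathrm{p}K_{a,n}$, the state with $i$ protons removed has

$$f_i = \frac{10^{\sum_{j \le i}(\mathrm{pH} - \mathrm{p}K_{a,j})}}
             {\sum_k 10^{\sum_{j \le k}(\mathrm{pH} - \mathrm{p}K_{a,j})}}.$$

```{r speciation}
molar_fractions(c(8.71, 14.59, 25.11), pH = 7.4)
```

Only macroscopic constants are treated — site-specific microconstants are
out of scope, since the deprotonation paths collapse to one macroscopic
ladder at this level. Activity coefficients are ignored (ideal-dilute
assumption); no ionic-strength correction is attempted. Note that published
speciation tables are sometimes computed from unrounded pKa values, so a
printed fraction pair (say 0.942/0.058) need not match what the printed
pKa reproduces (0.953/0.047 for pKa₁ = 8.71 at pH 7.4). The pipeline never
silently reconciles such differences: the *as-printed* mode (below) accepts
published fractions verbatim, and the *internal* mode computes its own.

## Exergonicity screening

Channels with ΔG° > 0 are omitted from the kinetics — even if fast, they
are easily reversible and contribute negligibly to scavenging. The
inequality is strict: ΔG° = 0 is retained. Channels that do not exist for a
species (the anion's deprotonated site, SET in a lipid phase) are encoded
explicitly with `present = FALSE` and carry no energetics; they are removed
silently, never counted as omitted. `screen_exergonic()` returns the
retained set, the omitted set, and a per-row report. Tabulated sign
conventions are followed exactly as given: a negative ΔG° is exergonic and
retained.

## TST rates and tunneling

Each retained FHT channel gets a conventional transition-state-theory rate

$$k = \sigma\,\kappa\,\frac{k_B T}{h}\,
      e^{-\Delta G^{\ddagger}/RT}$$

at the 1 M / 298.15 K standard state (`eyring_rate()`), with σ the
reaction-path degeneracy and κ the tunneling factor. Two tunneling models
are available per channel:

* `eckart_tunneling()` (default) — Boltzmann-averaged transmission through
  the asymmetric Eckart barrier whose forward and reverse heights are the
  activation free energies of the two directions (reverse =
  ΔG‡ − ΔG°) and whose width is set by the imaginary frequency.
* `wigner_tunneling()` — the leading curvature correction
  $1 + \frac{1}{24}\left(\frac{h c \tilde\nu}{k_B T}\right)^2$, used as a
  cross-check, a fallback, and the reference correction for synthetic
  fixtures.

Free energies, not enthalpies, parameterize the Eckart barrier here; the
choice is exposed per channel (`eckart` / `wigner` / `none`) rather than
hard-wired, since tabulated kinetic protocols differ on this point. SET
channels receive no tunneling correction (κ = 1).

## Marcus barriers for SET

SET channels have no locatable transition state; their barrier comes from
the Marcus parabolic free-energy relation

$$\Delta G^{\ddagger} = \frac{\lambda}{4}
   \left(1 + \frac{\Delta G^\circ}{\lambda}\right)^2,$$

with the reorganization energy λ supplied directly or derived from the
vertical electron-transfer energy as $\lambda = \Delta E_\mathrm{SET} -
\Delta G^\circ$. In the inverted region (ΔG° < −λ) the barrier is clamped
at 0 with a warning — the conventional treatment for thermal SET screening,
where a rising inverted-region barrier would be an over-interpretation of
the parabolic model.

## Diffusion corrections

Activation-controlled rates are capped by how fast the reactants encounter
each other: Stokes–Einstein diffusivities $D = k_BT/6\pi\eta a$ per
reactant, the Smoluchowski limit $k_D = 4\pi R_{AB} D_{AB} N_A$ at the
encounter distance, and the Collins–Kimball interpolation

$$k_\mathrm{app} = \frac{k_\mathrm{act}\,k_D}{k_\mathrm{act} + k_D}.$$

No electrostatic (Debye) factor is applied by default: the hydroperoxyl
radical is neutral, so every channel treated here has an uncharged partner.
No solvent-cage correction is applied for unimolecular encounters.

## Aggregation

Per species and solvent, $k_\mathrm{total} = \sum_i k_{\mathrm{app},i}$;
branching ratios are $\Gamma_i = 100\,k_i / k_\mathrm{total}$ and always
close to 100 %. In a lipid phase only the neutral species exists, so
$k_\mathrm{overall} = k_\mathrm{total}$. In water,

$$k_\mathrm{overall} = \sum_s f_s\,k_{\mathrm{total},s},$$

the molar-fraction-weighted sum over coexisting acid–base states, with
$k_f = f\,k_\mathrm{total}$ reported per state. `compare_to_reference()`
reports fold-changes against reference antioxidants both unrounded and
rounded to the nearest integer, the form in which such comparisons are
conventionally quoted.

# Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| temperature | K | 298.15 | standard kinetic reference state |
| water viscosity | Pa·s | 8.91×10⁻⁴ | literature value at 298.15 K |
| pentyl ethanoate viscosity | Pa·s | 8.62×10⁻⁴ | literature value at 298.15 K |
| solute radii | m | 2.0×10⁻¹⁰ | fixture-scale fallback; override for real solutes |
| reaction distance | m | sum of radii | contact encounter |
| tunneling | — | eckart | asymmetric-barrier average; `wigner`/`none` selectable |
| Eckart quadrature tolerance | relative | 10⁻⁸ | see numerics below |
| λ (SET reorganization) | kcal/mol | user-supplied | never printed alongside tabulated ΔG°; must come from the user |
| `apply_standard_state` | flag | `FALSE` | see below |

The 1 atm → 1 M standard-state shift ($RT\ln 24.46$ per unit molecularity
change, ≈1.89 kcal/mol at 298.15 K for a bimolecular activation) is
available as `standard_state_correction()` and as a config flag, but is
**off** by default: tabulated solution energetics are normally already at
the 1 M standard state, and published tables rarely say on which side of
the correction they sit. The flag stays user-visible precisely because that
ambiguity cannot be resolved by the software.

Physical constants are CODATA 2018 (the SI-exact defining constants),
centralized in `physical_constants()`; energies are internal kcal/mol with
the thermochemical calorie and 627.5095 kcal/mol per hartree.

# Numerical choices

* **Eckart Boltzmann average.** The raw energy-domain integrand
  $P(E)e^{-E/k_BT}$ spans tens of orders of magnitude, which defeats the
  error estimates of adaptive quadrature (a well-converged-looking result
  can be off by ~10⁻³ relative). The package substitutes
  $E = E_0 + k_BT\,s^2$, making the integrand analytic in $s$ at the lower
  endpoint (the Eckart wave numbers scale as $\sqrt{E - E_0}$, so the kink
  disappears) with Gaussian decay, and integrates by composite Simpson with
  interval doubling until the estimate moves by less than the tolerance.
  Transmission probabilities are evaluated in log space so large-barrier
  hyperbolic cosines cannot overflow. For vanishing curvature
  ($h c\tilde\nu < 0.05\,k_BT$) the transmission approaches a classical
  step no grid can resolve, and the average reduces analytically to the
  Wigner expansion, which is used directly.
* **Speciation in log₁₀ space.** Cumulative $\sum(\mathrm{pH} -
  \mathrm{p}K_a)$ exponents are normalized by their maximum before
  exponentiation, so pKa ladders spanning 25 units cannot overflow, and a
  monoprotic acid at pH = pKa returns exactly (0.5, 0.5).
* **Transition-state validity.** ΔG‡ ≥ max(0, ΔG°) is enforced with a
  10⁻⁶ kcal/mol tolerance at table construction — a transition state
  cannot lie below both endpoints.
* **Degenerate inputs.** Empty tables yield empty results or zero totals
  with explicit warnings, never errors; both Collins–Kimball rates zero
  returns zero; `k_D = Inf` means "no diffusion limit" and returns the
  activation rate; branching with $k_\mathrm{total} = 0$ is an error
  (undefined), not a silent zero.
* **Round-trip-exact I/O.** Tables are written with 17 significant digits,
  so write/read reproduces doubles exactly and unchanged configurations
  produce byte-identical outputs.

# Execution modes

`run_pipeline()` has two modes because two different questions arise:

* **internal** — recompute everything from raw energetics. This is the
  scientific pipeline; its absolute results depend on inputs (λ, radii,
  activation energies) that published tables often omit, so it is validated
  by properties and synthetic round trips rather than by reproducing any
  particular published absolute rate.
* **as-printed** — take published fractions and per-species totals at face
  value and perform only the aggregation arithmetic. This reproduces a
  published summary table exactly and keeps "checking the arithmetic"
  honestly separate from "recomputing the physics". Note the interaction
  with rounding: fold-changes between $k_f$ values computed from printed
  fractions and totals can differ in the last digit from folds between the
  *printed* (3-significant-figure) $k_f$ values themselves.

# The synthetic-data generator

`generate_fixture()` draws a complete fictional polyprotic phenolic
antioxidant: 1–4 acidic sites with prescribed pKa targets (isodesmic
inputs constructed by inverting the closed form, so the targets are
recovered exactly), per-site FHT channels in water and a lipid phase with
barriers, reaction energies and imaginary frequencies drawn uniformly
within stated ranges, endergonic SET channels, explicit absent channels,
and one lipid channel forced endergonic so the screening stage is always
exercised. Defaults mirror a triprotic gallate-bearing phenol: pKa
8.71/14.59/25.11, barriers 5–18 kcal/mol, ΔG° −14…+1 kcal/mol, 1000–3500
cm⁻¹, λ = 20 kcal/mol, pH 7.4, 298.15 K.

Its ground truth is computed inside the generator by straight-line
arithmetic from locally bound constants — deliberately *not* by calling the
pipeline functions — so a fixture round trip compares two independent
evaluations. Fixture kinetics use the Wigner correction because it has a
closed form any checker can re-derive to full precision; the Eckart path is
validated separately against a fine-grid trapezoid quadrature oracle.

What the generator does **not** emulate: correlated errors of
electronic-structure methods (its draws are independent and uniform by
design), conformational averaging, hindered-rotor corrections,
microspeciation, and solvent-dependent λ. A passing round trip therefore
demonstrates that the pipeline's composition of stages is mathematically
faithful, not that any particular quantum-chemistry protocol is accurate
for real compounds.

Problem sizes used in the shipped validation: three-site fixtures with two
solvents (12 channels), 50 random Eckart barriers against the quadrature
oracle, 100 random polyprotic systems against a mass-action equilibrium
solve, and 10³ random inputs for the bound and closure properties — sizes
at which every stage's behavior is already fully exercised.

# Known limitations

* Absolute $k_\mathrm{total}$ values from raw energetics require inputs
  (activation energies per site, λ, radii, encounter distances) that
  published summaries typically do not contain; without them the internal
  mode is only as good as the user's inputs.
* Marcus barriers use one λ per run; per-channel λ requires splitting the
  run.
* No Debye electrostatic correction and no ionic-strength dependence —
  adequate for neutral radicals, not for ion–ion encounters.
* The quantum-output reader supports exactly one dialect (the thermal
  free-energy summary line); anything else must be pre-tabulated.
* No uncertainty propagation: inputs are treated as exact.
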