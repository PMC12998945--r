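---
title: "Cryptic epistasis in enzyme kinetic ensembles: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cryptic epistasis in enzyme kinetic ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinepistasis)
```

## The model

An enzyme's catalytic cycle is parameterised by the Gibbs free energies
of its ground and transition states along the reaction coordinate. Every
microscopic rate constant is an Eyring/Arrhenius exponential of one
barrier,

$$k = \frac{k_B T}{h}\, e^{-\Delta G^\ddagger / RT},$$

so each rate constant is a strictly multiplicative function of the state
energies, while the composite kinetic parameters — $k_\mathrm{cat}$,
$K_M$, $K_D$, $k_\mathrm{cat}/K_M$ — mix sums and ratios of several rate
constants. That mixing is the entire source of the phenomenon this
package studies: two mutations whose free-energy effects add exactly
(hence whose effects on every *rate constant* multiply exactly) still
produce double-mutant *kinetic parameters* that deviate from the
multiplicative null prediction
$p_{12}^{null} = p_{wt}(p_1/p_{wt})(p_2/p_{wt})$. The deviation
$\varepsilon = p_{12}/p_{12}^{null}$ is non-specific (cryptic) epistasis:
it reflects the non-linear map from energies to observables, not any
physical interaction between the mutations.

Two mechanisms are implemented. The **simple** mechanism
(E + S ⇌ ES → E + P) has four states and three rate constants; its
$k_\mathrm{cat} = k_2$ and $K_D = k_{-1}/k_1$ are single exponentials or
ratios of exponentials and therefore provably free of non-specific
epistasis, while $K_M = (k_{-1}+k_2)/k_1$ and the efficiency are not.
The **complex** mechanism adds a reversible chemical step and
irreversible product release through an EP intermediate (five rate
constants); its $k_\mathrm{cat} = k_2k_3/(k_2+k_{-2}+k_3)$ now contains a
sum, so $k_\mathrm{cat}$ epistasis appears as well. $K_D$ keeps its
ratio form in both mechanisms and never shows epistasis — these two
exact nulls are asserted at relative tolerance $10^{-10}$ in the test
suite.

## Parameters that matter

* **Temperature** — 298.15 K by default, configurable everywhere. The
  reference free-energy profiles have no published temperature; 298.15 K
  together with CODATA $k_B$, $h$ and $R = 1.98720425\times10^{-3}$
  kcal mol⁻¹ K⁻¹ reproduces the reference wild-type tables (k_cat 11.5
  s⁻¹, K_M 255 µM, etc.) within 1.3%, which is the only calibration the
  choice needs. Tests assert 3%.
* **Wild-type profiles** — `simple_wt` = {E+S: 0, (E+S)‡: 10, ES: −5,
  (ES)‡: 11} kcal/mol; `complex_wt` adds {EP: −9, (E+P)‡: 9}. The free
  E+P state never enters any rate constant and is not represented.
* **Perturbation bounds** — uniform ±2 kcal/mol per state, the stated
  regime of the in silico mutagenesis; every rate-relevant state is
  perturbed independently, mirroring the empirical norm that one
  mutation shifts several barriers at once.
* **Fold thresholds** — 1.5 (primary, an experimental-noise proxy), 2,
  5, 10. Significance is symmetric: $|\log\varepsilon| \ge \log(1.5)$.
* **Library size** — n = 1000 singles, hence 499,500 unordered doubles.
  Pairs are unordered and self-pairs excluded; $\varepsilon$ is
  symmetric under swapping the mutations (asserted), so ordered
  enumeration would only duplicate every statistic.

## The bimolecular prefactor

The same $k_BT/h \approx 6.2\times10^{12}$ value is used for the
bimolecular binding step (units M⁻¹s⁻¹), with no diffusion-limit cap.
This deliberately allows $k_1$ above the diffusion limit; capping it
would change absolute rates but not the structure of the epistasis,
which depends only on fold-changes and on the $k_{-1}/k_2$ balance.

## Classification rule

Significant pairs are classified by how each mutation's effect behaves
across backgrounds: mutation 1's effect is $\log(p_1/p_{wt})$ in the
wild type and $\log(p_{12}/p_2)$ in the mutation-2 background. The
design question with no canonical answer is when a change of sign
between backgrounds counts as a "flip". Two rules were evaluated against
the published prevalence arithmetic of this model family:

* *strict sign* — any sign change is a flip. This over-counts sign
  epistasis badly (≈11% of all pairs vs the ≈5.6% that a 1.5-fold noise
  threshold implies), because a large beneficial effect that shrinks to
  a 0.9-fold residue technically changes sign while remaining
  indistinguishable from neutral.
* *thresholded flip* (adopted) — a flip requires the effect to exceed
  the same 1.5-fold threshold in magnitude in **both** backgrounds with
  opposite signs. Sub-threshold effects are treated as neutral, exactly
  as sub-threshold epistasis is. Under this rule the simulated class
  shares land within ±3 percentage points of the reference statistics
  for both mechanisms and for both efficiency and k_cat.

Zero flips → magnitude, one → sign, two → reciprocal sign. Class shares
are reported as percent of *all* pairs (so the three classes sum to the
prevalence), and the positive/negative split as percent of *significant*
pairs.

## What the generator emulates — and what it does not

The simulator emulates: additive free-energy mutational effects (the
empirically supported null for non-interacting mutations), mutations
touching all sub-states at once, and the resulting log-normal-like
spread of kinetic parameters. It does **not** emulate: measurement
noise (the fold threshold is a proxy, not an error model), specific
epistasis (by construction absent — which is the point), correlations
between a mutation's effects on different states, non-uniform effect
distributions, or mechanisms beyond the two implemented. A green
simulation test therefore establishes that the analysis pipeline
recovers the intrinsic ensemble epistasis of these two mechanisms under
the stated sampling — not that any particular enzyme behaves this way.

Seed-to-seed spread matters: with n = 1000 the 499,500 pairs are built
from only 1000 independent singles, so prevalence statistics carry a
standard deviation of roughly 1–2 percentage points across seeds (larger
for complex-mechanism k_cat). The acceptance bands (±3 pp) are bands
over fresh seeds, not numerical tolerances.

## The correction workflow

Given microscopic rate constants for wild type, both singles and the
double, the workflow computes kinetic parameters exclusively from rate
constants (measured parameters, when present, are only screened via the
symmetric fold error, flagged above 1.5). Three predictions are
compared per parameter: the multiplicative **null**; the **corrected
null**, i.e. parameters recomputed from multiplicatively combined rate
constants (what the double would show with zero specific epistasis);
and the **observed** parameters. The decomposition

$$\underbrace{\frac{obs}{null}}_{\text{apparent}} =
  \underbrace{\frac{corr.null}{null}}_{\text{non-specific}} \times
  \underbrace{\frac{obs}{corr.null}}_{\text{corrected specific}}$$

is an algebraic identity (asserted at $10^{-10}$). Rate constants
reported only as bounds are used at face value with a recorded warning.
For acyl-enzyme mechanisms where no reverse chemical rate is reported,
`k_minus2 = 0` is accepted and the complex-mechanism formulas reduce
accordingly.

## Numerical choices and degenerate inputs

* All pair computation happens on log-rate perturbations
  ($\Delta\log k = -\Delta\Delta G^\ddagger/RT$), so multiplicativity of
  the doubles' rate constants is exact to machine precision rather than
  accumulated through repeated exponentials.
* Validation rejects non-positive rates (except `k_minus2 = 0`),
  non-finite energies, non-positive temperatures, unsorted or ≤1
  thresholds, and effect vectors that do not cover every state; error
  messages name the offending state/field.
* An exactly zero log effect cannot flip (measure-zero under continuous
  sampling; relevant only for hand-constructed inputs).
* The closed-form $K_M$ surface is evaluated directly from the fold
  effects; its equality with the simulation pipeline on extracted folds
  is a cross-implementation test at $10^{-8}$.
* Grid scans default to 41 log-spaced points per axis over
  [0.01, 100] — resolution is a display choice, not a model parameter —
  with $\beta_1=\beta_2=1$ so each axis point maps to one
  $\alpha/\beta$ ratio and one $\varepsilon$; pass a vector of betas to
  scan all four folds.

## Known limitations

* Only the two mechanisms are implemented; no N-state generalisation,
  no progress-curve solver, no diffusion-limit correction.
* The k₋₁ sweep reports, but does not assert, the behaviour of the
  balanced point k₋₁ = k₂: on the bounded grid the maximum
  $\varepsilon$ there is ≈1.96, i.e. above a 1.5-fold threshold at
  extreme same-direction fold combinations, so "no positive epistasis
  when k₋₁ = k₂" holds only for moderate fold effects; the sweep's
  monotone growth of max $\varepsilon$ away from the balanced point is
  asserted.
* The correction workflow's published validation case relies on an
  external 1990 β-lactamase rate-constant table that is not
  redistributed here; the workflow is instead validated on synthetic
  cycles with injected specific epistasis and on the published
  fold-error spot checks.
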