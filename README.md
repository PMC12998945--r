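# kinepistasis

Non-specific ("cryptic") epistasis intrinsic to enzyme catalytic cycles:
simulation, classification, closed-form theory, and a correction workflow
for experimental double-mutant cycles.

## The problem

Epistasis inferred from enzyme kinetic parameters is routinely read as
evidence of a physical interaction between two mutations. But k_cat, K_M
and catalytic efficiency are *non-linear* functions of the free energies
of the catalytic cycle's ground and transition states. Even when two
mutations shift those free energies strictly additively — zero physical
interaction — the double mutant's composite parameters deviate from the
multiplicative null model. This package quantifies that intrinsic,
non-specific epistasis, and corrects experimental double-mutant cycles
for it so that genuine (specific) epistasis can be read off the
microscopic rate constants.

It is aimed at enzymologists and protein-evolution researchers analysing
double-mutant cycles, kinetic data sets, or fitness-landscape models
built on Michaelis–Menten kinetics.

## The model

A reaction coordinate assigns Gibbs free energies G (kcal/mol) to each
state of the cycle. For the simple mechanism
E + S ⇌ ES → E + P the states are E+S, the binding transition state
(E+S)‡, ES, and the chemical transition state (ES)‡. Each microscopic
rate constant follows transition-state theory,

    k = (k_B T / h) · exp(−ΔG‡ / RT),

giving k₁ (binding, M⁻¹s⁻¹), k₋₁ (unbinding) and k₂ (chemistry). The
composite parameters are

    k_cat = k₂,   K_D = k₋₁/k₁,   K_M = (k₋₁ + k₂)/k₁,
    k_cat/K_M = k₁k₂/(k₋₁ + k₂).

The complex mechanism adds a reversible chemical step and an
irreversible product release through an intermediate EP (rates k₋₂, k₃),
with

    k_cat = k₂k₃/(k₂ + k₋₂ + k₃),
    K_M   = (k₂k₃ + k₋₁k₋₂ + k₋₁k₃) / (k₁(k₂ + k₋₂ + k₃)).

A "mutation" perturbs every state's G by an independent uniform draw
(default ±2 kcal/mol). Doubles are built by summing two mutations' ΔG
vectors, so their microscopic rate constants are *exactly* multiplicative
— any epistasis in the composite parameters,

    ε = (p₁₂/p_wt) / ((p₁/p_wt)(p₂/p_wt)),

is non-specific. For K_M in the simple mechanism ε has the closed form

    ε = (α₁α₂k₋₁ + β₁β₂k₂)(k₋₁ + k₂) /
        [(α₁k₋₁ + β₁k₂)(α₂k₋₁ + β₂k₂)],

where αᵢ, βᵢ are mutation i's folds on k₋₁ and k₂; ε = 1 iff
(α₁−β₁)(α₂−β₂) = 0, and sign(ε−1) = sign((α₁−β₁)(α₂−β₂)).

## Worked example

A full in silico experiment — 1000 mutations on the simple wild type,
all 499,500 unordered doubles:

```r
library(kinepistasis)
sim <- simulate_epistasis("simple", n = 1000, seed = 1)
sim$summary
#> <epistasis_summary> simple mechanism, 499500 pairs (n = 1000)
#> parameter      1.5x     2x     5x    10x  mag/sign/recip (pos%)
#> k_cat          0.0%   0.0%   0.0%   0.0%   0.0/0.0/0.0 (-)
#> K_M           38.5%  27.6%   7.9%   2.6%  35.3/2.9/0.3 (40.3)
#> K_D            0.0%   0.0%   0.0%   0.0%   0.0/0.0/0.0 (-)
#> efficiency    38.5%  27.6%   7.9%   2.6%  33.8/4.2/0.5 (59.7)
```

Despite strictly additive free energies, ~38% of doubles show ≥1.5-fold
epistasis in catalytic efficiency (mostly magnitude epistasis, ~60% of it
positive), while k_cat and K_D show none — k_cat = k₂ is a single
exponential and K_D a ratio of two, both strictly multiplicative.

Correcting an experimental double-mutant cycle (synthetic example with a
known 5-fold specific boost injected into the double's k₂):

```r
f <- system.file("extdata", "synthetic_experiment.json", package = "kinepistasis")
rep <- correction_report(read_experiment(f))
rep
#> <correction_report> simple mechanism
#> specific epistasis per rate constant (observed/expected):
#>       k1 k_minus1       k2
#>        1        1        5
#>                 k_cat   K_M   K_D efficiency
#> null             4710 0.467 0.364   10100.00
#> corrected_null   4710 0.454 0.364   10400.00
#> observed        23500 0.814 0.364   28900.00
#> nonspecific_eps     1 0.972 1.000       1.03
#> apparent_eps        5 1.740 1.000       2.87
#> corrected_eps       5 1.790 1.000       2.79
```

The injected 5-fold k₂ interaction is recovered exactly; the apparent
K_M epistasis (1.74) splits into a non-specific ensemble part (0.97) and
a corrected specific part (1.79), with apparent = non-specific ×
corrected as an identity.

Command line (after install):

```sh
Rscript -e 'kinepistasis::kinepi_cli()' simulate --mechanism simple --n 1000 --seed 1 --out runs/simple
Rscript -e 'kinepistasis::kinepi_cli()' grid --kminus1 62.1 --k2 11.5 --out grid.csv
Rscript -e 'kinepistasis::kinepi_cli()' correct --input experiment.json --out report.json
```

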