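---
title: "Kinetic characterization of bisubstrate enzymes: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic characterization of bisubstrate enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzmech)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open.

## The biological problem

Pyruvate kinase (PK) catalyzes the final, ATP-yielding step of
glycolysis: phosphoryl transfer from phosphoenolpyruvate (PEP) to
ADP. *Vibrio cholerae* carries two active isozymes from the two
branches of the PK family: a K⁺-dependent enzyme (VcIPK, glutamate
at the monovalent-cation position) allosterically activated by
fructose 1,6-bisphosphate, and a K⁺-independent enzyme (VcIIPK,
lysine at that position) with essential activation by ribose
5-phosphate. Characterizing such a pair requires a chain of
quantitative steps — assay-mix speciation, saturation and
initial-velocity fitting, dead-end inhibition analysis, and
metabolite quantification — and this package implements that chain
as composable, individually tested operations.

## Speciation of the assay mix

The kinetically relevant species are not the pipetted totals:

* PEP is active as the fully ionized trianion PEP³⁻. The package
  partitions total PEP by a single Henderson–Hasselbalch
  equilibrium, `pep3 = pep_total / (1 + 10^(pK − pH))`, with pK 6.3
  by default. No PEP–metal or PEP–K⁺ binding is modeled: the
  speciation is a deliberate single-equilibrium model, not a general
  chelation calculator.
* The nucleotide substrate is the 1:1 ADP–metal complex. Given
  totals A₀ and M₀ and a dissociation constant K_d, the complex is
  the physically valid (smaller) root of
  `x² − (A₀+M₀+K_d)x + A₀M₀ = 0`, evaluated in the
  cancellation-free form `2A₀M₀/(S + sqrt(S² − 4A₀M₀))` so the mass
  balances hold to better than 10⁻⁹ mM even when binding is nearly
  quantitative.
* The inverse path (`compose_for_targets()`) converts target free
  species back to totals, because bench protocols are written in
  free-species terms but executed in totals.

**Dissociation-constant defaults.** The K_d values shipped in
`speciation_constants()` — 0.38 mM for ADP-Mg and 0.10 mM for ADP-Mn,
appropriate near 0.1–0.3 M ionic strength — are configurable
defaults, not measurements made here; any result that depends on
them should be reported together with the constant used, and the
characterization report records them for that reason.

**Ionic strength.** `ionic_strength()` computes `μ = ½Σcᵢzᵢ²` over an
explicit species list and refuses to guess: a species missing from
the charge table is an error naming it. The composition-level
convention in `speciate()` is: monovalent cations and the divalent
metal enter as chloride salts (counter-ions included), TMACl
contributes both ions, PEP and ADP species enter at their formal
charges, and buffer (HEPES), NADH and substrate counter-ions are
excluded by default (a constants switch adds substrate
counter-ions). This is a bookkeeping convention — the assays the
package emulates hold μ constant with TMACl, so only differences
matter in practice.

**Known discrepancy.** Published free-PEP³⁻ figures for these assay
media (e.g. 30.8 mM from 40 mM total at pH 7.0) are lower than the
pure Henderson–Hasselbalch value (33.35 mM), and are mutually
inconsistent across conditions; the correction originally applied
(ionic strength, metal binding, or temperature) is not stated
anywhere we could verify. The package implements the pure
single-equilibrium calculation and documents the difference rather
than reverse-engineering an unstated correction.

## Rate laws

Four closed forms cover every fitted model:

* **Hill**: `v = Vmax·Sⁿ/(K₀.₅ⁿ + Sⁿ)`. At S = K₀.₅ the velocity is
  Vmax/2 for any n; n = 1 is Michaelis–Menten.
* **Rapid-equilibrium random-order bisubstrate**:
  `v = Vmax·A·B/(K_aK_b + K_a·B + K_b·A + A·B)` with A = PEP³⁻ and
  B = ADP–metal. In double-reciprocal space, lines at fixed B have
  slope `K_a(1+K_b/B)/Vmax` and intercept `(1+K_b/B)/Vmax`, so the
  family intersects at exactly (−1/K_a, 0).
* **Linear dead-end inhibition**:
  `v = Vmax·S/(K_m(1+I/K_i) + S(1+I/(αK_i)))`. One evaluator serves
  all three modes: competitive is the α→∞ limit (slope effect only),
  noncompetitive is α = 1, mixed type has α free. The single code
  path makes the nesting exact: mixed type at α = 1 is bit-identical
  to noncompetitive. The α convention follows the dead-end analysis
  this package reimplements: α < 1 means the enzyme–inhibitor binary
  complex binds the other substrate *more* tightly than free enzyme
  (some texts invert this; reports state the convention).
* **Type Ib monovalent activation**:
  `kcat(M) = basal + (kcat_max − basal)·M/(K_act + M)`. Whether the
  original fits carried a nonzero basal term is not documented;
  `basal` defaults to 0 and is a free option.

Velocity units ("umol_min_mg" specific activity vs "per_s" turnover)
are carried as tags on parameter objects and datasets; the
inhibitor/K_i pair likewise carries a unit tag, and silent unit
mixing is an error rather than a wrong number.

## Fitting

All estimation is unweighted (optionally relative-weighted)
least squares by Levenberg–Marquardt, on **log-transformed
parameters**: every kinetic parameter here is positive, and the log
scale enforces that bound without constrained optimization or
ad-hoc clipping. Starts are data-driven (Vmax at 1.1× the maximal
observed velocity, K at the concentration nearest half-maximal
velocity, n and α at 1) with five starts log-spaced over ±1 decade
around the K heuristic; the best-deviance solution wins. Noiseless
round trips recover generating parameters to well below the 0.1%
the tests require.

Standard errors are asymptotic, from a central-difference Jacobian
of the residuals at the optimum; they are computed on the log scale
and mapped back by the delta method. Confidence intervals
(`confint_kin_fit()`) are built on the log scale and exponentiated,
so they are positive and asymmetric like the sampling distribution
of a positive parameter. Under the generator's default multiplicative
noise the matched estimator is the relative-weighted one, and with
it the 95% intervals bracket the generating truth in ≈92–96% of
seeded replicates (checked over 200 seeds in the test suite); the
unweighted estimator's intervals under-cover slightly (≈88%) because
its homoscedastic error model is then misspecified. Replicate-level
spread (the "SD of three experiments" of a bench table) is a
different statistic and can be computed from replicate fits.

**Turnover convention.** `kcat_from_vmax()` converts specific
activity to a per-oligomer turnover with the oligomer mass
`monomer_mass × n_subunits`; the default tetramer (n = 4) is the
convention that reproduces the published turnovers (476 μmol·min⁻¹·mg⁻¹
× 4 × 53,138 Da → 1686 s⁻¹ against a printed 1684 s⁻¹, 0.2%
agreement from rounded inputs). Catalytic efficiencies are reported
as log₁₀(k_cat/K_m) with K_m in molar.

## Mechanism inference

`reciprocal_lines()` fits ordinary least-squares lines through
(1/[S], 1/v) per fixed co-substrate level, dropping zero-velocity
points with a warning (their reciprocals are undefined) and
requiring ≥ 3 points per line and ≥ 2 lines.
`classify_initial_velocity()` pools all pairwise intersections and
calls the family *parallel* when the relative slope spread is within
`tol`, *intersecting on the 1/S axis* when the pooled |y| is within
`tol` of the vertical scale 1/Vmax (estimated as the smallest
intercept) and x < 0, and above/below the axis otherwise. The
defaults — `tol = 0.05`, dispersion bound 0.5 — are configurable
because no tolerance is inherited from the original (visual)
analysis; noiseless families classify at machine precision, while
at 5% CV the pairwise intersections of a small grid scatter enough
that the classifier may honestly return `indeterminate` rather than
overcommit.

`classify_inhibition()` automates what a bench analysis does by eye,
with an explicit statistical criterion: all candidate modes are fit
globally; competitive and noncompetitive (3 parameters each) are
tested against mixed type (4 parameters) by extra-sum-of-squares
F-tests at α = 0.05 (AICc is reported alongside); a reduced model
also counts as adequate when its fit is numerically perfect (RSS
below 10⁻⁹ of the velocity variance), which makes noiseless round
trips deterministic instead of hinging on a 0/0 F statistic. Among
adequate models the most parsimonious wins; a mixed call is
subdivided by the fitted α against 1 (±0.05 band). Slope and
intercept replots against [I] must be linear (relative curvature
≤ 0.05), otherwise the classification is rejected with a
"non-linear replot" diagnostic — the linear inhibition models do not
apply to such data.

`infer_mechanism()` encodes the dead-end rule table: intersecting
initial-velocity patterns plus each analog competitive against its
own substrate and noncompetitive/mixed against the other (both
analogs required) ⇒ rapid-equilibrium random order; an analog
competitive against *both* substrates ⇒ ordered addition with its
substrate first; everything else ⇒ indeterminate, with the
conflicting rules listed. Intersecting initial-velocity patterns
alone cannot distinguish ordered steady-state from random
rapid-equilibrium addition, so the label is never assigned without
dead-end evidence.

## Metabolite quantification

Stepped coupled assays add one coupling enzyme at a time to a
cuvette; each addition converts one analyte stoichiometrically with
1:1 NAD(P)H turnover, so each plateau-to-plateau ΔA₃₄₀ measures one
metabolite: `Δc = ΔA/(ε·path)`, scaled by cuvette volume and extract
dilution to micromoles in the extract. ε = 6.22 mM⁻¹cm⁻¹ (the
standard NAD(P)H value) and the per-step stoichiometry registry are
data, not code. Plateaus moving against the stated direction are an
error naming the step. The Rib 5-P assay's donor (commercial
xylulose 5-phosphate) is itself contaminated with Rib 5-P
(40–50% in the original determinations; default fraction 0.45), and
`correct_rib5p()` subtracts it, flooring at zero and flagging the
assay as failed when the correction exceeds the apparent amount by
more than 10%.

Intracellular concentrations divide extract amounts by total cell
volume: cell count from A₆₀₀ (6×10⁸ cells·ml⁻¹ at A₆₀₀ = 0.7,
linear in between) times a single-cell volume from a spherocylinder
model, `V = π(w/2)²(L−w) + (π/6)w³` (1 μm³ = 1 fL). The cell-volume
equation and the cell dimensions behind the published intracellular
table are not printed in our source, so cell dimensions are
user-supplied and the published concentrations serve only as
round-trip material for the generator — they are not reproduction
targets of this package.

## Synthetic data: what it emulates and what it does not

The generators produce every dataset shape the pipeline consumes,
with the study's printed designs as defaults: the monovalent-cation
series (1–100 mM), the PEP³⁻ × ADP-Mg grid (5×5, 0.06–1.21 mM ×
0.15–1.5 mM) and the PEP³⁻ × ADP-Mn grid (0.0408–0.81 mM ×
0.025–1.3 mM). The default noise model is multiplicative with CV 5%
and 3 replicates — emulating triplicate spectrophotometric
initial-velocity assays with typical scatter, since no noise
magnitude is documented for the original data. Generation is
seed-deterministic and does not disturb the session RNG stream.

What passing tests on synthetic data show: the estimators invert
the generators (round-trip identity), the classifiers recover
generating modes, and interval coverage is calibrated *under the
assumed noise model*. What they do not show: robustness to coupled
assay lag artifacts, substrate depletion during the read,
LDH-limitation under oxalate inhibition, day-to-day Vmax drift, or
any systematic (non-random) error — none of which the noise model
emulates.

## Problem sizes and numerical choices

The test suite runs entirely from code-built fixtures: speciation is
verified against a brute-force mass-action grid scan (iterative
refinement to 10⁻⁶ mM resolution) on 1000 random triples; the full
mechanism pipeline is exercised on 50 random parameter draws;
interval coverage uses 200 seeded triplicate datasets. Where a test
or script needs an inhibition design that the original study does
not print, substrate levels are placed geometrically around K_m
(0.25–8×) and inhibitor levels at 0–4×K_i (or the stated 0–30 μM for
oxalate) — spanning both sides of each constant so all parameters
are identified. These sizes
keep the whole suite under ~10 s on one core while leaving the
statistical checks well-powered. Convergence tolerances for the LM
runs are 10⁻¹⁴ (relative) with at most 500 iterations; fits that do
not converge are flagged on the result object, never raised as
exceptions.

## Known limitations

* Speciation is single-equilibrium by design: no ATP/EGTA/pH-coupled
  chelation network, no activity-coefficient corrections.
* Each effector concentration is fitted as a separate curve; there
  is no joint allosteric model across effector levels (MWC/KNF
  fitting is out of scope).
* The inhibition classifier assumes linear (first-order in I)
  inhibition; parabolic inhibition is rejected via the replot check
  rather than modeled.
* Pattern classification on small noisy grids is conservative;
  pooled-intersection dispersion beyond the bound returns
  `indeterminate` instead of a forced call.
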