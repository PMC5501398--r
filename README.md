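# enzmech

Kinetic characterization of bisubstrate enzymes with allosteric
activation, built around the analysis used to characterize the two
pyruvate kinase isozymes of *Vibrio cholerae* (VcIPK, a K⁺-dependent
enzyme activated by fructose 1,6-bisphosphate, and VcIIPK, a
K⁺-independent enzyme with essential activation by ribose
5-phosphate). The package is for enzymologists who need to go from
pipetted assay compositions to fitted kinetic constants and a named
Cleland mechanism, with every intermediate step testable against
synthetic data.

## What it does

- **Speciation** — rate laws take free species, not totals. The
  package converts total PEP, ADP and divalent metal into PEP³⁻
  (Henderson–Hasselbalch, pK 6.3 by default), the ADP–metal complex
  and free metal (1:1 mass action with configurable K_d), both
  forward and inverted (target free species → pipettable totals),
  and balances ionic strength with TMACl.
- **Rate laws** — Hill saturation
  `v = Vmax·Sⁿ/(K₀.₅ⁿ + Sⁿ)`; rapid-equilibrium random-order
  bisubstrate
  `v = Vmax·A·B/(K_a·K_b + K_a·B + K_b·A + A·B)`;
  linear dead-end inhibition
  `v = Vmax·S/(K_m(1+I/K_i) + S(1+I/(αK_i)))` with one evaluator for
  competitive (α→∞), noncompetitive (α=1) and mixed (α free) modes;
  and hyperbolic (type Ib) monovalent-cation activation.
- **Fitting** — multi-start Levenberg–Marquardt least squares on
  log-parameters (positivity enforced by the scale): single-curve
  Hill fits, global bisubstrate fits, global inhibition fits, with
  asymptotic standard errors and log-scale Wald intervals. Derived
  scalars: per-tetramer k_cat from specific activity, log₁₀(k_cat/K_m)
  efficiencies, activation folds.
- **Mechanism inference** — double-reciprocal line families,
  intersection-pattern classification, F-test model selection among
  the inhibition modes with replot-linearity checks, and the
  dead-end rule table that names the mechanism
  (`rapid_equilibrium_random`, `ordered_A_first`, `ordered_B_first`
  or `indeterminate`).
- **Metabolite quantification** — stepwise coupled-assay absorbance
  traces (one NAD(P)H per analyte) decoded to micromole amounts,
  Rib 5-P donor-contamination correction, and intracellular
  concentrations via cell counts and a spherocylinder cell-volume
  model.
- **Synthetic data** — seeded generators for every dataset shape,
  with the study's printed concentration designs as defaults and a
  configurable noise model (default: multiplicative, CV 5%,
  triplicates).

## Worked example

Speciate an assay mix, fit a noisy synthetic initial-velocity grid,
and classify its double-reciprocal pattern:

```r
library(enzmech)

comp <- assay_composition(pep_total = 5, adp_total = 7.735,
                          metal_identity = "Mg", metal_total = 8.5,
                          monovalent = c(K = 90), ph = 7.0)
speciate(comp)
#> Speciated assay mix (mM):
#>   pep3               4.16831
#>   pep_protonated     0.831688
#>   adp_metal_complex  6.5
#>   metal_free         2
#>   adp_free           1.235
#>   ionic_strength     131.728

balance_ionic_strength(131.7, 300)   # TMACl (mM) to reach 300 mM
#> [1] 168.3

truth <- bisubstrate_params(476, 0.3, 0.5)      # umol/min/mg, mM, mM
grid  <- gen_bisubstrate_grid(truth, metal = "Mg",
                              noise = default_noise(seed = 42))
fit_bisubstrate_global(grid, weighting = "relative")
#> Nonlinear fit: random_bi model, 75 points, rss = 0.2183
#>       estimate  std_error
#> vmax 472.99000 11.4320000
#> ka     0.29927  0.0088985
#> kb     0.49087  0.0173020

classify_initial_velocity(reciprocal_lines(gen_bisubstrate_grid(truth)))
#> Pattern call: intersecting_on_1S_axis
#>   pooled intersection (-3.333, -4.337e-20), dispersion (7.52e-15, 8.18e-18)
```

The fitted triple recovers the generating truth within its standard
errors; the noiseless reciprocal family intersects on the 1/[S] axis
at −1/K_a = −3.33 mM⁻¹, the signature of rapid-equilibrium
random-order substrate binding. Converting the fitted Vmax with the
53,138 Da monomer mass of the type I enzyme:

```r
kc <- kcat_from_vmax(472.99, monomer_mass_da = 53138, n_subunits = 4)
catalytic_efficiency(kc, 0.29927)
#> kcat = 1676 s^-1, log10(kcat/Km_PEP) = 6.75
```

`run_characterization()` ties the stages together: it takes a
manifest of datasets with roles (saturation curves, a bisubstrate
grid, dead-end inhibition grids, activation pairs) and returns one
report with the parameter tables, derived scalars and the inferred
mechanism.

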