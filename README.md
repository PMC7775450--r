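# glycobind

Quantitative models of how cationic nanocapsules interact with the
polyanionic glycocalyx of mammalian cells.

Highly charged glycosaminoglycans such as heparan sulphate (up to ~4
charges per nm) exceed the Manning threshold for counterion
condensation: mobile counterions collapse onto the chain and screen
most of its charge. For a cell surface this has a counterintuitive
consequence — at low doses, positively charged nanocapsules see only
the *effective* (screened) charge and bind weakly; above a critical
particle concentration the condensed counterions are released, binding
sites open up, and binding accelerates before saturating. The result
is a cooperative dose–binding curve whose shape encodes the initial
line charge density of the glycocalyx.

`glycobind` implements this analysis end to end for researchers in
nanomedicine and cell biophysics:

* **Manning theory.** Charge spacing `b = L/P`, Bjerrum length
  `l_B = e² / (4π ε₀ ε k T)` (≈ 0.714 nm in water at 25 °C),
  dimensionless line charge density `ξ = l_B / b`, the condensation
  criterion `ξ > 1`, and the condensed-charge fraction `1 − 1/ξ`.
* **Condensation-gated binding model.** Available-site fraction
  `f(c) = 1/ξ_eff(c)` rising from `1/ξ₀` to 1 around the critical
  concentration `c*`; mean binding signal
  `B(c) = b_max (1 − exp(−(s/b_max) ∫₀ᶜ f(u) du))`; fitting recovers
  `ξ₀`, `c*`, `b_max` and the intrinsic slope `s`, plus a
  cooperativity index and a chain-length estimate from `c*`.
* **Vacuole kinetics.** Hill model
  `N_v(t) = N_v,max · tⁿ / (kⁿ + tⁿ)` for intracellular vacuole
  formation after uptake of drug-loaded capsules; the metric `k⁻¹` is
  the cells' drug-deposition ability.
* **ECIS decomposition.** Impedance model
  `Z(t) = Z₀ + Z_max e^(−t/a) − N_v(t)` separating nanocapsule binding
  (decay constant `a`; `a⁻¹` = binding ability) from vacuole
  formation, with component segregation and convergence/identifiability
  flags.
* **Image quantification.** ImageJ-style mean-dark and triangle-dark
  auto-thresholds, frame-difference motility index, vacuole area per
  cell, and a PSF-deflation spot detector for glycan-cluster density
  in super-resolution images.
* **Synthetic data.** Seeded generators for every stage (dose–binding
  curves, impedance traces, vacuole time-courses, STED-like cluster
  fields, jittering live-cell stacks) with known ground truth, so the
  whole pipeline is testable without any measured data.

## Worked example

```r
library(glycobind)

## Manning parameters of heparan sulphate in water at 25 °C
line_charge_density(0.25)
#> Manning condensation state
#>   charge spacing b:       0.25 nm
#>   Bjerrum length:         0.714 nm
#>   line charge density xi: 2.856
#>   condensed:              yes (xi > 1)
#>   condensed fraction:     0.6498
#>   effective charge frac.: 0.3502

## simulate a strongly condensed dose-binding experiment and refit it
cur <- gen_binding_dataset("t24_control", seed = 1)   # xi0 = 4.2 truth
fit <- fit_condensation_model(normalize_curve(cur))
fit
#> Condensation binding model fit
#>   xi0:        4.34 (SE 0.45)
#>   c*:         2.68e+11 (SE 2.2e+10) particles/mL
#>   b_max:      103 (SE 3.1) %
#>   slope_high: 2.96e-10 (SE 3.2e-11) % per particle/mL
#>   residual norm: 3.625;  converged: TRUE

cooperativity_index(normalize_curve(cur))$ratio
#> [1] 3.29
```

The fitted `xi0 = 4.34 ± 0.45` recovers the generating initial line
charge density 4.2 — strong counterion condensation — and the critical
concentration `c* = 2.68e11 particles/mL` matches the generating
2.6e11. The cooperativity ratio (high-regime slope over low-dose
slope) is well above the 1.5 classification threshold.

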