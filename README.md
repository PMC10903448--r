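# gatekin

Binding and permeability kinetics for calmodulin-gated water channels.

Aquaporin-0 (AQP0), the dominant water channel of the lens, is gated by the
Ca²⁺ sensor calmodulin (CaM), and phosphorylation of the AQP0 C-terminal
helix (serines 229, 231, 235) tunes that gating. Quantifying this requires
three quantitative assays, each with its own model:

- **Stopped-flow shrinkage → osmotic permeability.** Proteoliposome
  light-scattering traces are fitted with a bi-exponential
  `y = y0 + A1·exp(−k1(x−x0)) + A2·exp(−k2(x−x0))`; the fast rate,
  corrected for empty-liposome background and reconstitution efficiency
  (`k1_adj = (k1_meas − k1_ctrl)/(N1·N2)`), gives the water permeability
  `Pf = k1 / ((S/V0)·VW·C_out)`.
- **MST binding curves → equilibrium affinity.** Exact ligand-depletion
  isotherms: the one-to-one quadratic-root model
  (`y = S1 + (S2−S1)·Lfree/(Lfree+KD)`) and a two-to-one cooperative model
  built on the partition function `Q = 1 + L/KD1 + L²/(KD1·KD2)` with
  numerically solved free ligand, plus AICc model selection and a
  principled `no_binding` call. `KD2 < 4·KD1` flags positive cooperativity.
- **SPR sensorgrams → kinetics.** Two-stage global fitting of two-process
  kinetics: bi-exponential dissociation (`R = A1·e^(−koff1·t) +
  A2·e^(−koff2·t)`, off-rates shared across concentrations), then
  association with off-rates fixed
  (`R = ΣCi(1 − e^(−(c·koni + koffi)t))`), giving `KDi = koffi/koni` and
  the geometric-mean overall affinity `√(KD1·KD2)`.

Group comparisons use a Z-test for population means,
`Z = (X̄1−X̄2)/√(σ1²+σ2²)`. Seeded simulators for all three assay types
(including a physical vesicle-shrinkage ODE mode and a full-study fixture
writer) make every stage testable without instrument data.

## Worked example

Simulate a 12-point MST dilution series (0.2–17 µM titrant at 32 nM
labelled partner) from the one-to-one model and fit it back:

```r
library(gatekin)

series <- build_dilution_series(17e-6, 12,
                                implied_dilution_factor(17, 0.2, 12),
                                partner_conc = 32e-9)
curve <- simulate_mst_curve("1to1",
                            list(s1 = 900, s2 = 845, kd = 1.49e-6),
                            series, noise_rel = 0.002, seed = 42)
fit_mst_curve(curve$conc, curve$fnorm, series$partner_conc, model = "auto")
#> MST binding-curve fit: one_to_one
#>   KD = 1.31 uM (se 0.18 uM)
#>   RSS = 21.14 over 12 points
```

The recovered affinity (1.31 ± 0.18 µM) agrees with the generating 1.49 µM
within its standard error; at 0.2% multiplicative noise on the raw
fluorescence scale a single series determines KD to roughly ±15%.

Permeability from a simulated shrinkage trace (100 nm vesicles,
400 mOsm/L external osmolality):

```r
geom <- vesicle_geometry(100)            # S/V0 = 3e5 1/cm
k1 <- pf_to_k1(365 / 1e4, geom$sv0, vw = 18, c_out = 4e-4)  # 78.84 1/s
trace <- simulate_shrinkage_trace("empirical",
           list(y0 = 0.05, a1 = 0.75, k1 = k1, a2 = 0.2, k2 = 1.5),
           duration = 5, rate = 1000, noise_sd = 0.01, seed = 42)
fit <- fit_double_exponential(trace$time, trace$signal)
#> Bi-exponential fit: k1 = 79.67 1/s, k2 = 1.498 1/s
pf_um_per_s(compute_pf(fit$k1, geom$sv0, vw = 18, c_out = 4e-4))
#> [1] 369
```

A 369 µm/s estimate from a trace generated at 365 µm/s with 1% noise:
the fast rate and the Pf formula invert each other. Comparing wild-type
permeability with and without Ca²⁺/CaM:

```r
z_test(365, 35.0, 126, 27.7)
#> Z = 5.355, two-sided p = 8.58e-08 (significant at alpha = 0.05)
```

`make_study_fixture(dir, seed = 1)` writes a complete synthetic study
(traces, MST curves, sensorgrams, truth manifest) in the package's file
dialects; `inst/cli/gatekin.R` wraps the pipeline for shell use
(`simulate`, `fit-permeability`, `fit-mst`, `fit-spr`).

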