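---
title: "Models and methods behind gatekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gatekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatekin)
```

gatekin quantifies how calmodulin (CaM) gates the lens water channel
aquaporin-0 (AQP0), and how phospho-mimicking mutations of the AQP0
C-terminal helix (S229D, S231D, S235D) change that regulation. Three assay
types feed the pipeline: stopped-flow light-scattering shrinkage of
proteoliposomes (osmotic water permeability), microscale thermophoresis
(MST) binding curves (equilibrium affinity), and surface plasmon resonance
(SPR) sensorgrams (binding kinetics). This vignette explains each model, the
parameters that matter, the numerical choices, and what the bundled
simulators do and do not emulate.

## Osmotic permeability from vesicle shrinkage

When proteoliposomes are rapidly mixed with hyperosmotic buffer they shrink,
and the 90° scattered-light intensity rises. The averaged, normalised trace
is described by a bi-exponential,

$$y(t) = y_0 + A_1 e^{-k_1 (t - x_0)} + A_2 e^{-k_2 (t - x_0)},$$

where the faster rate $k_1$ reports water efflux through the reconstituted
channel and the slower $k_2$ the background liposome population.
`fit_double_exponential()` profiles the linear parameters ($y_0$, $A_1$,
$A_2$) out of the least-squares problem and optimises only the two
log-parameterised rates (variable projection). This makes the fit immune to
amplitude/offset start values and leaves a two-dimensional, well-behaved
search space, which is multi-started on a log-spaced rate grid spanning
`0.1/span` to `2/dt`. Rates are sorted after fitting so $k_1 \ge k_2$
always; supplying the components in the opposite order changes nothing. A
free time offset $x_0$ is not identifiable jointly with the amplitudes
(only $A_i e^{k_i x_0}$ enters the model), so $x_0$ is fixed at the first
sample.

The fast rate is corrected for the empty-liposome background and for the
amount of protein actually incorporated, measured by Western-blot
densitometry as a between-construct factor $N_1$ (normalised to wild type)
and a within-construct replicate factor $N_2$:

$$k_{1,\mathrm{adj}} = \frac{k_{1,\mathrm{meas}} - k_{1,\mathrm{ctrl}}}{N_1 N_2}.$$

The grouping of this expression is genuinely ambiguous in its typeset form.
We read it as above — subtract the background, then rescale to
reference-construct loading — because the alternative literal reading
$k_{1,\mathrm{meas}} - k_{1,\mathrm{ctrl}} N_1 N_2$ leaves the measured rate
uncorrected for loading, which defeats the purpose of the densitometry.
Both readings are implemented (`adjust_k1(mode = "ratio")`, the default,
and `mode = "literal"`).

Permeability follows from the standard vesicle-shrinkage relation

$$P_f = \frac{k_1}{(S/V_0)\, V_W\, C_\mathrm{out}},$$

with $S/V_0 = 3/r$ for a sphere (extrusion through a 200 nm filter gives
$r \approx 100$ nm, the default), $V_W = 18\ \mathrm{cm^3\,mol^{-1}}$ the
partial molar volume of water, and $C_\mathrm{out}$ the external osmolality
after mixing in $\mathrm{osmol\,cm^{-3}}$. The alternative grouping
$k_1 (S/V_0) V_W C_\mathrm{out}$ is dimensionally wrong for a velocity and
is not offered. $C_\mathrm{out}$ has no safe default in general; mixing 1:1
with an 800 mOsm osmolyte solution gives the $4\times10^{-4}$
osmol cm$^{-3}$ used throughout the examples.

Group differences are assessed with a Z-test for population means,
$Z = (\bar X_1 - \bar X_2)/\sqrt{\sigma_1^2 + \sigma_2^2}$, two-sided
against the standard normal, significant at $\alpha = 0.05$. The reported
uncertainties are used as the $\sigma$ inputs exactly as given; with
triplicate-based spreads this is approximate, but it is the convention the
permeability comparisons are defined by.

## Equilibrium binding with ligand depletion

MST titrations hold the labelled partner (CaM-Alexa488, `p_tot`, typically
32 nM final) fixed while the titrant (AQP0 monomer, `l_tot`) is diluted
serially. At these partner concentrations depletion matters and the free
titrant must be solved, not approximated by the total.

**One-to-one.** The mass balance gives a quadratic whose physical root is

$$L_\mathrm{free} = \tfrac12 (L_\mathrm{tot} - P_\mathrm{tot} - K_D)
  + \sqrt{\tfrac14 (K_D + P_\mathrm{tot} - L_\mathrm{tot})^2
          + L_\mathrm{tot} K_D},$$

and the signal interpolates the free and saturated endpoint signals,
$y = S_1 + (S_2 - S_1)\, L_\mathrm{free}/(L_\mathrm{free} + K_D)$. The
root is evaluated in a cancellation-free rational form when
$K_D + P_\mathrm{tot} > L_\mathrm{tot}$, keeping the mass-balance residual
below $10^{-9}$ relative across the full parameter range.

**Two-to-one.** One CaM can engage two AQP0 C-terminal helices. With
stepwise macroscopic dissociation constants $K_{D1}$ (first site) and
$K_{D2}$ (second), the partner partitions over free, singly and doubly
bound states with partition function
$Q = 1 + L/K_{D1} + L^2/(K_{D1} K_{D2})$, and the signal is the
population-weighted sum $y = S_0 f_0 + S_a f_1 + S_b f_2$. The free-ligand
mass balance $L_\mathrm{tot} = L + P_\mathrm{tot}(f_1 + 2 f_2)$ is strictly
increasing in $L$, so `solve_free_ligand_2to1()` brackets the unique root
on $[0, L_\mathrm{tot}]$ (`uniroot`, tolerance $10^{-12} L_\mathrm{tot}$).
This is the minimal parameterisation carrying exactly the two constants the
assays report; how the original software bookkept the three species signals
is not published, so the species-signal parameterisation here is a design
choice. With $K_{D2} \to \infty$ and $S_a = S_2$ the model collapses to the
one-to-one form, which is property-tested.

For two identical, independent sites the statistical factor alone forces
$K_{D2} = 4 K_{D1}$; `classify_cooperativity()` therefore calls
$K_{D2} < 4 K_{D1}$ positive cooperativity.

**Fitting and model selection.** `fit_mst_curve()` fits either model by
Levenberg–Marquardt with log-parameterised constants, multi-started on
8 log-spaced $K_D$ values spanning a tenth of the lowest to ten times the
highest concentration (the two-site model screens a start grid of constant
pairs by residual sum of squares and polishes the best six). With
`model = "auto"` both models are fitted and compared by small-sample
corrected AICc; ties go to the simpler model. A curve is reported
`no_binding` when any of three conditions holds:

1. fitted amplitude $\le 3\times$ the median-absolute-deviation residual
   scale (no signal change beyond noise);
2. fitted $K_D$ more than 10× the top concentration (no approach to
   saturation inside the measured range);
3. the standard error of every fitted dissociation constant exceeds its
   estimate (the affinity is formally inside the window but carries no
   information — flat noisy curves occasionally produce such fits, with
   relative errors of several hundred percent, and reporting them as
   affinities would be misleading).

**Dilution design.** `build_dilution_series()` produces final (post 1:1
mixing) concentrations $c_i = c_\mathrm{top}/f^{i-1}$. The default factor is
1.5 because 12-point series spanning, e.g., 0.18–16 µM or 0.2–17 µM imply
$f = (c_\mathrm{top}/c_\mathrm{bottom})^{1/11} \approx 1.5$; a strict 2:1
series over 12 points would span three and a half orders of magnitude.
Both factors are supported and `implied_dilution_factor()` recovers the
factor from a printed range.

**Uncertainty.** The fit standard error (from the LM covariance) and the
spread across replicate dilution series measure different things; both are
reported (`summarize_mst_replicates()`), and no claim is made about which
one a given published ± corresponds to.

## Two-process SPR kinetics

Sensorgrams of AQP0 flowed over immobilised CaM need two kinetic processes.
Whether these are two AQP0 protomers engaging one CaM (cooperativity) or
one protomer bridging two chip CaMs (avidity) cannot be decided from the
data, so the summary reports both constants, their geometric mean
$\sqrt{K_{D1} K_{D2}}$ as the overall affinity, and the cooperativity
classification, without asserting mechanism.

Fitting is two-stage, matching the parameterisation the equations define:

1. **Dissociation first.** All dissociation phases (time re-zeroed at the
   end of injection, no offset term) are fitted globally to
   $R(t) = A_1 e^{-k_\mathrm{off1} t} + A_2 e^{-k_\mathrm{off2} t}$ with
   the two off-rates shared across analyte concentrations and amplitudes
   free per curve. Processes are sorted fast-first. If one process carries
   under 0.5% of the amplitude the fit falls back to a flagged
   single-exponential.
2. **Association with off-rates fixed.**
   $R(t) = \sum_i C_i\,(1 - e^{-(c\,k_\mathrm{on,i} + k_\mathrm{off,i}) t})$,
   on-rates shared, amplitudes free per curve. Fixing $k_\mathrm{off,i}$ in
   the exponent pairs the fast dissociation with the fast association
   process by construction.

Both stages use variable projection (amplitudes solved linearly for any
candidate rates) so the nonlinear search is only ever two-dimensional, with
a log-spaced rate-pair screen (off-rates $10^{-6}$–$1\ \mathrm{s^{-1}}$,
4 per decade) before polishing. Flow cells are analysed independently and
aggregated as mean ± SD (`aggregate_kinetics()`).

**What is and is not identifiable.** The 120-minute dissociation phase pins
both off-rates tightly (median error < 5% at 0.5 RU noise in the property
suite). The on-rates are weaker: when $k_\mathrm{obs} t_\mathrm{inj}$ is
small, a curve's early rise constrains only the product
$C_i k_\mathrm{obs,i}$, and since each amplitude is free the on-rate is
determined only by the curvature of the most concentrated curves. At the
simulated response scale (~100 RU maximal) and 0.5 RU noise this leaves
median on-rate errors in the tens of percent — the fitted values sit at the
global residual minimum, so this is estimator variance inherent to the
design, not an optimisation failure. Derived $K_{D}$ values inherit this
spread, which is why the dissociation-dominated slow process and the
geometric-mean affinity are the robust summaries.

## The simulators

`simulate_mst_curve()` and `simulate_sensorgram_set()` evaluate exactly the
forward models above (multiplicative Gaussian noise for Fnorm, additive for
RU; sensorgrams are continuous at the end of injection by construction).
`simulate_shrinkage_trace()` has two modes: `"empirical"` draws from the
bi-exponential observation model; `"physical"` integrates the osmotic
volume equation for a sphere of fixed surface area,

$$\frac{dV}{dt} = -P_f\, S\, V_W \left(c_\mathrm{out} -
  \frac{n_\mathrm{in}}{V}\right),$$

with the internal osmolyte amount conserved, and maps volume to signal as
$(V_0 - V(t))/(V_0 - V_\infty)$ — any monotone mapping would do since the
empirical fit is scale-free; this one keeps the clean signal in $[0,1]$. A
small slow exponential component can be added to emulate the background
liposome population that makes real traces bi-exponential. Linearising the
ODE about equilibrium gives a relaxation rate
$P_f (S/V_0) V_W\, c_\mathrm{out}^2/c_\mathrm{in}$, which for small
gradients is the same rate the $P_f$ formula inverts; the property suite
checks the fitted rate against this at $c_\mathrm{out}/c_\mathrm{in} = 1.1$
within 10%.

`make_study_fixture()` writes a full synthetic study: 5 constructs
(wild type, three mutants, empty-liposome control) × 4 buffer conditions ×
3 replicate traces; triplicate 12-point MST series per binding construct;
3 SPR flow cells per construct with measurable binding; plus a JSON truth
manifest. The built-in truth encodes the expected effect structure:
wild-type permeability drops ~2.4-fold only under Ca²⁺ + CaM, mutants are
insensitive, wild-type MST truth is two-to-one (increasing curve), S231D
one-to-one (decreasing curve), S229D/S235D flat. Replicate-level
permeability is jittered with an 8% coefficient of variation, matching the
~10% relative spreads typical of triplicate reconstitutions; default trace
noise is 0.01 a.u. on unit-normalised signals, MST noise 1% multiplicative
on the raw fluorescence scale, SPR noise 0.5 RU.

**What the simulations do not show.** The generators share their functional
form with the fitted models (apart from the physical trace mode), so round
trips demonstrate correctness of the estimation machinery, not robustness
to model misspecification: no vesicle polydispersity, no SPR baseline
drift or mass-transport limitation, no thermophoresis physics behind the
Fnorm values. One consequence worth knowing: at 1% multiplicative noise on
a realistic raw Fnorm scale (offset ~900, amplitude ~55) a single 12-point
series often cannot distinguish the two-to-one from the one-to-one model,
and single-series $K_D$ errors reach tens of percent — comparable to the
±30% uncertainty the real experiment reports. The amplitude-relative noise
setting (unit signals) is the appropriate regime for testing recovery of
the machinery itself.

## Problem sizes and reproducibility

The bundled property suites use 100 seeded MST curves, 50 seeded sensorgram
sets (sampled every 20 s), and traces of a few thousand points — sizes
chosen so the whole suite exercises every code path in well under a minute
while leaving the stochastic medians stable. Every generator takes an
integer `seed` and restores the global RNG state afterwards, so any
simulated dataset is a pure function of its arguments. Concentrations are
molar everywhere inside the package; µM/nM appear only at I/O boundaries
(`read_table()` converts `conc_um` columns on load).
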