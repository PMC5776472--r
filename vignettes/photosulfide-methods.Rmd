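---
title: "Kinetic control of oxygenic and anoxygenic photosynthesis under sulfide: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic control of oxygenic and anoxygenic photosynthesis under sulfide: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(photosulfide)
```

## The biological problem

Some filamentous cyanobacteria from sulfidic habitats switch between two
photosynthetic modes: ordinary oxygenic photosynthesis, in which water is
split at the oxygen-evolving complex (OEC) of photosystem II (PSII), and
anoxygenic photosynthesis, in which sulfide is oxidized to zero-valent
sulfur by a sulfide:quinone oxidoreductase (SQR) that feeds electrons into
the plastoquinone (PQ) pool and onward through photosystem I (PSI).  The
two modes interact through three mechanisms this package models explicitly:

1. **Sulfide poisons PSII.**  H2S binds a reactive intermediate of the OEC
   formed during water oxidation, so even trace sulfide (~1 uM) shuts
   oxygenic production down completely; release of the bound sulfide is
   slow, producing a long recovery lag after the water column is again
   sulfide-free.
2. **Light sets the ceiling for anoxygenic rates.**  Sulfide oxidation can
   only run as fast as PSI can re-oxidize the chain, so the maximum
   anoxygenic rate rises with irradiance; the *initial slope* of the rate
   versus H2S curve is light-dependent too, which a single static SQR
   cannot produce.
3. **Sulfide modulates carbon fixation.**  Moderate H2S enhances electron
   transport downstream of PSI (anoxygenic rates can reach about twice the
   oxygenic maximum at optimal light), while high H2S (above roughly
   44 uM) inhibits it again.

The package encodes these mechanisms as a deterministic ODE system,
simulates the laboratory experiments used to characterize such strains
(microsensor light-dark shifts, sulfide injections, DCMU treatments,
photosynthesis-irradiance curves, diel cycles), implements the
corresponding rate-extraction procedures, and calibrates the model to rate
datasets.

## State variables and conservation

The state (see `model_state()`) contains five conserved pools, each
normalized to total 1:

* PSII in ground, excited and degraded states (`psii_g`, `psii_e`,
  `psii_d`) — photoinhibition moves excited PSII to the degraded state,
  repair returns it;
* the OEC in active, oxidized-intermediate and H2S-inhibited states
  (`oec_a`, `oec_ox`, `oec_i`);
* oxidized/reduced plastoquinone (`pq_ox`, `pq_red`);
* an intermediate carrier 'ET' between PQ and PSI (`et_ox`, `et_red`),
  standing for cytochrome b6f / plastocyanin / cytochrome c553;
* NADP+/NADPH (`nadp`, `nadph`).

plus local H2S and O2 concentrations (uM) and two cumulative counters
(zero-valent sulfur produced, carbon fixed).  Every electron-transport
rate is kept in **electron-equivalent uM/s**; O2 and sulfide fluxes are
derived by dividing by 4 and 2.  This makes the 4-electrons-per-O2 and
2-electrons-per-sulfide conversions of the rate-extraction stage exact by
construction.

Fraction pools need a scale to couple to fluxes: the `*_tot` capacities
(electron-equivalent uM) convert an electron flux into a pool-fraction
turnover.  Steady-state rates are independent of these capacities; they
only set transient relaxation times.  The defaults (0.2–0.4 uM) make the
redox carriers relax within roughly a second, consistent with the
sub-second sensor response the light-dark shift method relies on: after
darkening, continued sulfide oxidation into the finite PQ/ET/NADP
reservoir stops within ~1 s, so slope-based rate extraction sees a crisp
transition.

## Rate laws

The process rates (`rate_vector()`) are minimal mass-action or Michaelis
forms consistent with the qualitative dependencies of the network; they
are isolated behind one function so alternates can be swapped:

| rate | form | meaning |
|------|------|---------|
| `k_L` | `f2 E psii_g` | PSII excitation |
| `k_OP` | `k_op_cat psii_e oec_a pq_ox` | PQ reduction by PSII (0 under DCMU) |
| `k_O2` | `k_o2 oec_ox oec_tot / 4` | O2 release from the OEC intermediate |
| `k_D` | `k_d_max psii_e E/(K_dE+E)` | photoinhibition, saturating in light |
| `k_R` | `k_r psii_d` | PSII repair |
| `k_S1` | `k_s1 oec_ox [H2S]` | OEC inhibition by H2S |
| `k_S2` | `k_s2 oec_i` | deinhibition |
| `k_AP` | `v_sqr alpha m_s(H2S) pq_ox` | SQR, `alpha` light factor in variant A |
| `k_AP2` | `v_uso m_u(H2S) et_ox` | second sulfide oxidase (USO), variant B |
| `k_PQ` | `k_pq pq_red et_ox` | PQ reoxidation |
| `k_PSI` | `f1 (1+beta pq_red) E et_red nadp` | PSI turnover with excitation transfer |
| `k_CO2` | `v_co2 gamma delta nadph/(K_nadph+nadph)` | CO2 fixation (NADPH sink) |

with `m_s`, `m_u` Michaelis terms, `gamma = 1 + gamma_amp [H2S]/(K_E+[H2S])`
(sulfide enhancement of carbon fixation) and `delta = K_I/(K_I+[H2S])`
(sulfide inhibition); `K_E < K_I` is enforced so enhancement saturates
before inhibition dominates.  Two design choices deserve comment:

* **Degradation–inhibition coupling is emergent.**  The photoinhibition
  rate depends only on excited PSII and light.  When the OEC is
  sulfide-blocked, excitation cannot be discharged photochemically, the
  excited fraction rises, and degradation accelerates — no explicit OEC
  term is needed in `k_D`.
* **`gamma` and `delta` act as a joint multiplier on `k_CO2`.**  Whether
  the enhancing and inhibiting effects of sulfide target the same or
  different Calvin-cycle steps is unknown; a joint multiplier is the
  most parsimonious reading and is what the calibration constrains.

The two sulfide-oxidation variants embody the two competing explanations
for light-dependent initial GAP slopes: variant "A" makes SQR activity
itself light-regulated (`alpha`); variant "B" adds a second, higher
affinity oxidase (USO, default Michaelis constant ~4 uM vs 100 uM for SQR)
donating downstream of PQ, whose throughput is throttled by PSI at low
light.  Setting `alpha_amp = 0` (or `v_uso = 0`) yields the single-SQR
null model used as the reference in variant discrimination.

## Default calibration

The shipped defaults (`model_params()`) are a single, versioned
calibration chosen so that the model jointly reproduces the headline
behaviours of the organism: oxygenic production maximal near
137 umol photons m-2 s-1 and suppressed by sub-micromolar H2S; anoxygenic
rates peaking near 44 uM H2S at optimal light at about twice the oxygenic
maximum, while staying below the oxygenic maximum at
36 umol photons m-2 s-1; and a ~30 min recovery lag after sulfide
depletion.  The calibration was obtained by minimizing a feature-distance
over these behaviours with a derivative-free simplex search; the SQR
Michaelis constant is fixed at 100 uM, inside the 50–200 uM apparent
range such strains exhibit.  `analysis/01_pi_curve.R` through
`analysis/06_calibration.R` regenerate every one of these behaviours from
the installed package, and `scripts/acceptance.R` recomputes the
quantitative anchors.

Key tunables and their defaults:

* `Km_sqr = 100` uM, `v_sqr` (electron uM/s) — SQR kinetics;
* `v_uso`, `Km_uso ~ 4` uM — the high-affinity downstream oxidase;
* `gamma_amp`, `K_E ~ 7` uM, `K_I ~ 74` uM — sulfide effects on carbon fixation;
* `k_s1 = 0.02` /(uM s), `k_s2 ~ 1.6e-5` /s — OEC inhibition fast at
  micromolar sulfide but soft enough that sub-0.05 uM traces permit
  oxygenic photosynthesis (steady suppression below 1% of the maximum is
  reached near 0.3 uM); release on a ~1 h timescale sets the ~30 min
  recovery lag;
* `k_d_max`, `K_dE`, `k_r` — photoinhibition/repair; their ratio sets the
  degraded fraction at each irradiance and hence the declining limb of
  the PI curve and the light dependence of recovery;
* `f2`, `f1`, `beta` — light capture of the two photosystems and
  PQ-redox-state-dependent excitation transfer between them.

## Numerical choices

Integration uses `deSolve::lsoda` with rtol 1e-8 / atol 1e-10.  Light
switches, injections and DCMU addition are handled by restarting the
integration exactly at each event time, so the state is continuous across
events while rates may jump.  Steady states double the integration
horizon until the maximum relative pool change drops below 1e-6 per 100 s
(non-convergence is flagged, never silent).  For the blocked-PSII
condition (DCMU or a fully inhibited OEC), the three-carrier subsystem's
stationarity collapses to a single monotone equation in the reduced PQ
fraction, which `.steady_gap()` solves by bisection to near machine
precision; the test suite cross-checks this algebraic route against the
full ODE steady state and against a brute-force fixed-step Euler
integration, so no result depends on a single solver.

The calibration objective is a sum of squared relative residuals with
equal per-curve weight — the inverse-variance weighting implied by the
generator's multiplicative noise — minimized by Nelder–Mead on
log-transformed parameters (all
kinetic constants are positive scale parameters) with bound clamping,
from a small Latin-hypercube multistart; runs are deterministic given a
seed.  With GAP data only, the recovery constants `k_s2` and `k_r` are
structurally unidentifiable and are reported as unconstrained rather than
fitted.  The SQR Michaelis constant is only weakly identified from rate
curves: below the anoxygenic optimum the high-affinity oxidase and the
chain's self-regulation buffer the saturation shape, and above it the
carbon-fixation ceiling hides it, so a noise-free refit recovers the
generating value almost exactly while 5% noise spreads single-fit
estimates over roughly a factor of two — mirroring the breadth of the
admissible 50–200 uM apparent range.  Fits under variant B therefore hold
the USO Michaelis constant at its structural (high-affinity) value and
bound the two enzymes' affinities apart; otherwise the enzymes are
exchangeable and neither constant is meaningful.  The Eilers-type PI fit `P(E) = E/(aE^2+bE+c)` exploits the fact
that `E/P` is linear in `(E^2, E, 1)`: an ordinary linear regression
provides deterministic starting values, refined by Levenberg–Marquardt.

## The synthetic-data generator

`generate_trace()` and `generate_fit_dataset()` emulate the measurement
process, not just the model: sulfide injections with first-order mixing
and outgassing, programmed light-dark shifts, DCMU treatments, and the
four experimental irradiances (23, 36, 137, 180 umol photons m-2 s-1).
Sensor noise is Gaussian and independent per sample with defaults
anchored to stated detection limits (O2 0.3 uM, H2S 0.2 uM, pH 0.005) at
0.25 s sampling; rate-level replicate variability (default 5%,
log-normal) represents biofilm-to-biofilm variation.  Rate datasets are
produced by running the simulated traces through the same extraction
code used for real data, so extraction bias is part of what calibration
tests must tolerate.  pH is a baseline 7.2 plus a small bounded term
following photosynthetic activity with a ~1 min response — enough to
exercise sulfide speciation (`S_tot = [H2S](1+10^(pH-pK1))`, pK1 6.98),
not a carbonate-chemistry model.  Because the medium is pH-buffered,
biological consumption of total sulfide drains the measured H2S channel
through the constant speciation factor.

What the generator does *not* emulate: electrode drift physics, stirring
artifacts, spatial gradients within the biofilm (the model is a lumped
surface layer; the diel simulation inherits this approximation), and
carbonate/pH feedback.  Passing tests on synthetic data therefore
demonstrate the internal consistency of model, extraction and
calibration — not field realism of any particular parameter value.

## Problem sizes

The test suite and the analysis scripts run everything at the sizes a
desk check needs: PI curves on ~12–20 point grids, GAP curves at 4–7 H2S
levels per irradiance, 10 synthetic datasets for parameter recovery,
recovery simulations of 3–6 h simulated time, and one 24 h diel cycle.
These choices keep a full run in minutes on one core while leaving every
qualitative regime (light limitation, CO2 limitation, photoinhibition,
OEC trapping and release) represented.

## Known limitations

* The diel forcing (half-sinusoid, constant sulfide supply flux) is a
  schematic of a mat's day, not a fitted reconstruction.  With a constant
  supply the surface layer never reaches exactly zero sulfide, so the
  default supply flux (2e-4 uM/s) is sized so the midday residual falls
  below the oxygenic-recovery threshold.  The simulated morning switching
  lag (~20 min) is somewhat shorter than the recovery-experiment lag
  (~30 min) because overnight darkness leaves PSII undamaged and the OEC
  largely untrapped at dawn.
* The recovery lag's light-independence is approximate: the 5% crossing
  time mixes OEC release (light-independent) with the degree of
  photoinhibition accumulated during exposure (light-dependent), so the
  lag at 23 umol photons m-2 s-1 is somewhat shorter than at 137.
* The OEC is a three-state lump, not a Kok cycle; excitation-energy
  quenching and state transitions beyond the `beta` factor are out of
  scope, as is 1-D reaction–diffusion structure in the biofilm.
* Variant discrimination is reported through residual sums of squares
  and parameter plausibility, not a formal information criterion — the
  underlying argument is qualitative (a static single SQR cannot bend
  the initial slopes), and the SSE ratio expresses it adequately.
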