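---
title: "Modelling mixed DPP6a/DPP6K channel kinetics with isakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mixed DPP6a/DPP6K channel kinetics with isakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isakit)
```

## The problem

The A-type potassium current of cerebellar granule neurons (I_SA) is
carried by Kv4.2 channels in complex with KChIP and DPP6 auxiliary
subunits. Two DPP6 N-terminal variants dominate in these cells and pull
the channel in different directions: DPP6a contributes an N-terminal
peptide that produces fast open-channel block (N-type inactivation),
while DPP6K slows recovery from inactivation and shifts steady-state
inactivation (SSI) to more hyperpolarized potentials. A channel complex
carries several DPP6 positions — plausibly two (DPP6 dimerizes in
solution) or four (one per Kv4 subunit) — so when both variants are
expressed, channels assemble as a mixed population and the measurable
gating of the population constrains the stoichiometry.

`isakit` implements the quantitative machinery this argument needs:
fixed-voltage Markov gating schemes and their relaxation analysis,
composition-resolved stoichiometry models, a per-subunit Boltzmann-shift
model of SSI, the curve-fitting conventions used on voltage-clamp
records, and a seeded synthetic-data generator that stands in for the
recordings.

## Gating schemes and relaxation analysis

A gating scheme is a continuous-time Markov chain over conformational
states; here the schemes are stars centred on the open state O with
inactivated branches I_a (N-type, DPP6a-mediated), I_K (DPP6K-mediated)
and I_int (intrinsic). All rates are fixed-voltage first-order constants
in s⁻¹: the models describe the post-peak decay at a strong
depolarization, not voltage-dependent activation. Internally everything
is SI (seconds, s⁻¹); milliseconds appear only at I/O and reporting
boundaries, which avoids the classic mixed-unit bug between ms time
constants and s⁻¹ rates.

The generator (Q-matrix) follows the row convention: entry (i, j) is the
i→j rate and diagonals make rows sum to zero, so row occupancy vectors
evolve as dp/dt = pQ. Equilibrium occupancy solves pQ = 0 with Σp = 1
via a QR solve of the augmented system. Any linear observable (we mostly
use the conducting-weighted open probability) relaxes as a sum of
exponentials whose time constants are reciprocals of the nonzero
eigenvalues of Q; `relaxation_spectrum()` returns those components and
`simulate_occupancy()` provides exact trajectories for cross-checking.

Numerical choices:

* The **fast time constant** is defined as the reciprocal of the
  largest-magnitude nonzero eigenvalue. On the one-DPP6a schemes this
  reproduces the quoted 11.6 / 8.7 / 11.6 / 8.75 ms predictions exactly
  at their printed precision (the test suite and `reproduce_report()`
  recompute them).
* Eigenvalues equal to within 1e−9 relative are merged into a single
  component (amplitudes summed); amplitudes below 1e−12 of the t = 0
  observable are dropped as numerical dust.
* Non-reversible schemes can have complex eigenvalue pairs. The full
  complex eigendata are kept internally so reconstruction is exact; the
  reported component table collapses conjugate pairs to τ = −1/Re(λ)
  with the real summed amplitude.
* If the eigenbasis is ill-conditioned (reciprocal condition below
  1e−10 — effectively a defective generator), the code falls back to a
  dense matrix-exponential propagation with amplitudes re-estimated by
  least squares, and flags `diagnostics$defective`. Star schemes with
  positive rates are reversible trees and never hit this path.

Channel-level rates derive from a fast-component fit by
k_ON = f_i/τ_i and k_OFF = (1 − f_i)/τ_i, so k_ON + k_OFF = 1/τ_i and
the equilibrium inactivated fraction equals f_i. These relations, with
(τ_i = 6 ms, f_i = 0.71) for DPP6a-only channels and
(35 ms, 0.74) for DPP6K-only channels, reproduce the published rounded
constants (30 s⁻¹ per subunit over four sites, 48 s⁻¹ per channel;
intrinsic 21 s⁻¹). The published intrinsic OFF-rate is quoted as
7.5 s⁻¹ although (1 − 0.74)/0.035 = 7.43 s⁻¹; the model presets use the
quoted 7.5 s⁻¹ so that predictions match the published parameterization.

## Stoichiometry models

Two models translate a subunit composition (n_a DPP6a, n_K DPP6K on
n_sites ∈ {2, 4} positions) into a scheme:

* **model1** — full proportionate ON-rate: O→I_a at n_a·k_a_on and
  O→I_K at n_K·k_K_on, channel-level OFF-rates unchanged. Defaults
  (s⁻¹): 4 sites (30, 48, 5.8, 7.5); 2 sites (60, 48, 11.6, 7.5).
* **model2** — DPP6a-only proportionate ON-rate: the N-type branch
  scales with n_a while a composition-independent intrinsic branch is
  always present. Defaults: 4 sites (25, 52, 21, 7.5); 2 sites
  (50, 52, 21, 7.5).

Branches with zero ON-rate are omitted, so a DPP6a-free model2 channel
is the pure two-state intrinsic relaxation (τ = 1/(k_on + k_off) ≈
35 ms) and compositions are never padded with unreachable states.

Assembly over compositions is binomial in the DPP6a mole fraction x_a,
with an optional bias factor: P(n_a) ∝ C(n_sites, n_a)(b·x_a)^{n_a}
(1−x_a)^{n_sites−n_a}, renormalized. The mole fraction of subunit
protein is taken equal to the cRNA mass ratio (a 1:9 mix gives
x_a = 0.1) — nothing in the source analysis defines it otherwise — and
b defaults to 1 (exact binomial); b = 2 is the documented preset for the
scenario in which DPP6a-containing channels are over-represented in
recordings by about two-fold. Compositions with probability below 1e−9
are pruned from population sums.

`population_decay()` mixes composition trajectories by assembly weight
(with a segregated mode for the no-co-assembly null hypothesis), and
`population_fast_weight()` reports the percentage of population
inactivation attributable to the fast N-type pathway. The amplitude
convention behind the published predicted population fast weights is
not specified in the source, so both defensible conventions are
exposed — the fast weight of a bi-exponential fit to the population
decay, and the equilibrium fraction of inactivation residing in I_a
states — and neither is asserted to reproduce those predictions.

A note on a limiting property: weakening the second branch
(k_K_on → 0) of a one-DPP6a model1 channel *lengthens* the fast time
constant toward the two-state value 1/(k_a_on + k_a_off) — the second
branch can only add relaxation rate. The test suite asserts this
monotone direction together with the closed-form limit.

## The per-subunit SSI shift model

Availability follows a first-order Boltzmann,
1/(1 + exp((V − V½)/S)) for inactivation (the activation convention
rises with voltage; exponents are clamped at ±700 to stay finite). The
shift model assumes an equal energetic contribution per incorporated
DPP6K subunit: the midpoint moves by ΔV = −2.3 mV per subunit,
obtained as (V½(all-K) − V½(all-a))/n_sites = (−72.4 + 63.3)/4 =
−2.275 ≈ −2.3 mV. The base (all-DPP6a) curve defaults to V½ = −63.3 mV,
S = 4.3 mV.

For a mole-fraction mix, the population availability is the
binomial-weighted sum of shifted Boltzmanns; fitting a single Boltzmann
back to that sum and regressing fitted midpoints on DPP6K mole fraction
yields a line of slope n_sites·ΔV ≈ −9.2 mV per unit mole fraction with
|residual| below 0.05 mV — midpoint linearity is exact by construction
to within fit precision. The refit grid defaults to −110…−30 mV in 2 mV
steps, spanning every midpoint the fixtures use with several points per
e-fold.

One subtlety the tests quantify: summing Boltzmanns whose midpoints are
binomially dispersed *broadens* the refit curve. With the default
parameterization the refit slope is exact at the pure compositions and
deviates most at equal mixing (about 4.53 vs 4.3 mV, a ~5.4% change) —
small, but not below every nominal band one might draw; we assert the
exact-endpoint and maximum-at-equal-mixing structure rather than a
round-number cap. For comparison, measured mixture slopes in the source
tables sit at 4.5 mV.

## Curve-fitting conventions

Decay fits model y(t) = Σ Aᵢ exp(−(t−t₀)/τᵢ) + C from the trace peak
onward and report τ-n with relative weights W-n = 100·Aᵢ/(ΣA + C) and
steady fraction W-ss = 100·C/(ΣA + C); the fast fractional inactivation
used by the rate derivations is f_i = W-1/100. Initial time constants
are log-spaced over the window and initial amplitudes come from linear
least squares given those taus, so every fit is a deterministic pure
function of its data — repeated calls are bit-identical. Optimization
uses Levenberg–Marquardt (minpack.lm) with tight tolerances
(ftol = ptol = 1e−14) so noiseless round trips recover parameters to
1e−6 relative. Negative fitted amplitudes are flagged and refit under
non-negativity bounds.

The choice between one and two components operationalizes "the fitted
curve deviated significantly" as a nested-model F-test at α = 0.05 —
the source states no criterion, so the conventional one is used.

Recovery fits constrain R(t) = 1 − Σ wᵢ exp(−t/τᵢ) with Σwᵢ = 1. The
weight split is weakly identified when one component dominates (e.g. a
91/9 split), so the fitter scans a small fixed grid of starting values
(four weight splits × two tau spacings) and keeps the best final fit —
deterministic, no random restarts.

Boltzmann fits fix the maximum at 1 by default; a free-maximum option
exists because experimentally normalized SSI points divide by the
most-hyperpolarized sweep, whose own availability sits slightly below
1 (noticeably so for broad curves, e.g. S = 8.4 mV at a −120 mV
reference) — the free amplitude absorbs exactly that normalization.
Constant inputs and direction-mismatched data error or flag (slope
bound hit) rather than returning garbage.

The peak-over-area estimator implements the subtract-then-measure
procedure for the average fast time constant: fit slow + steady
components on the tail (by default beyond ~5× the expected fast τ),
subtract the extrapolated slow model, and divide the remaining fast
component's trapezoidal area by its peak. For a pure exponential over a
window of length T this returns τ(1 − e^{−T/τ}) — a documented
truncation bias below 0.005% at T = 10τ.

## The synthetic generator

The generator emulates exactly the statistical structure the analysis
assumes: bi-exponential decays with a steady component, two-pulse
recovery families whose measured fractional recovery follows the
generating R(t) exactly in the noiseless case (the second pulse is the
first-pulse model scaled between its residual and peak), SSI prepulse
families scaled by Boltzmann availability, and Markov-scheme decays
bridging the stoichiometry models into the fitting pipeline. Fixture
presets carry the published parameter sets for the native granule-cell
current and each oocyte-expressed complex, transcribed once into
`inst/extdata/fixture_presets.tsv` and unit-tested against that copy.

Noise is additive i.i.d. Gaussian with σ expressed as a fraction of
peak — the minimal assumption, since the source states no noise model —
and every stochastic draw is seeded (`withr::with_seed`), making outputs
bit-identical per (parameters, seed). Activation kinetics are not
simulated: the rise is instantaneous at the test step because the
models describe post-peak inactivation only.

What passing tests do and do not show: noiseless round trips prove the
fitting pipeline inverts the generator's model family without bias, and
noisy recovery experiments (e.g. median τ₁ error under 5% at 1% noise
over 20 seeds) show robustness to well-behaved noise. Real records
additionally contain capacitance transients, series-resistance and
space-clamp artifacts, drift, and correlated noise, none of which the
generator emulates — agreement here validates the analysis code, not
any claim about biology.

Problem sizes used by the default suite were chosen to keep a full run
comfortable on a laptop: 1-second decays at 10 kHz sampling, 50 random
schemes for the spectral-oracle property, 100 random draws for
identifiability, and 20-seed noise sweeps.

## Interfaces and scope decisions

This is an analysis library, not a shell tool, so the command surface is
the exported functions — `stoich_predict()`, `ssi_mix()`,
`reproduce_report()`, the generators and fitters — organized
tidyverse-style: data frames in, tibbles out, broom-style
`tidy()`/`glance()` methods and `autoplot()` figures for fit objects.
Schemes and sweep sets serialize to plain text (JSON; CSV with a JSON
sidecar, printed at 9 significant digits for bit-identical round trips)
because the original acquisition formats are proprietary binaries.

Out of scope by design: voltage-dependent rate expressions (the models
are fixed-voltage), single-channel stochastic simulation, dwell-time
likelihood fitting, reading ABF/WCP binaries, series-resistance or
capacitance modelling beyond scaled-null subtraction, and any estimation
of rate constants from mixed-ratio dose–response data by optimization.

## Known limitations

* The stoichiometry models are two- and three-state stars; they capture
  the fast component's dependence on composition but compress slower
  processes into single branches.
* The per-subunit SSI model shifts midpoints only; slope differences
  between pure variants (4.3 vs 3.7 mV) are deliberately not modelled,
  and the binomial-broadening effect described above is an intrinsic
  consequence of that simplification.
* Population fast-weight conventions are reported, not adjudicated —
  the definitive convention would need the original analysis scripts.
* The generator's noiseless recovery construction makes round trips
  exact by matching the measurement convention (residual taken at the
  final sample); analyses of real traces should widen the residual
  window to average noise.
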