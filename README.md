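# isakit

Kinetic modelling and voltage-clamp trace analysis for the
somatodendritic A-type potassium current (I_SA).

Neuronal I_SA is carried by Kv4 channel complexes assembled with KChIP
and DPP6 auxiliary subunits. The DPP6 N-terminal variants matter: DPP6a
carries an N-terminal inactivation peptide that confers ultra-fast
N-type ("ball-and-chain") inactivation, while DPP6K slows recovery from
inactivation and hyperpolarizes steady-state inactivation (SSI). Because
a channel carries several DPP6 positions (2 or 4), co-expression of
DPP6a and DPP6K produces a binomial population of mixed channels, and
the channel's gating becomes a stoichiometry question. `isakit` is for
electrophysiologists and modellers who want to analyse such currents
and test stoichiometry hypotheses quantitatively.

## What it implements

**Markov gating schemes and Q-matrix relaxation.** A gating scheme
(states O, I_a, I_K, I_int with first-order rates, in s⁻¹) maps to a
generator matrix Q with rows summing to zero; occupancies evolve as
dp/dt = pQ. Any linear observable relaxes as

    obs(t) = steady + Σⱼ aⱼ exp(−t/τⱼ),   τⱼ = −1/λⱼ,

with λⱼ the nonzero eigenvalues of Q. The *fast inactivation time
constant* is the reciprocal of the largest-magnitude nonzero eigenvalue.
Channel-level rates derive from a fast-component fit via
k_ON = f_i/τ_i, k_OFF = (1−f_i)/τ_i.

**Stoichiometry models.** Two schemes for mixed DPP6a/DPP6K channels:
*model1* (full proportionate ON-rate: both branches scale with their
subunit counts) and *model2* (DPP6a-only proportionate ON-rate plus a
composition-independent intrinsic branch), each parameterized for 2 or 4
DPP6 sites with published rate constants. Assembly across compositions
is binomial in mole fraction, with an optional DPP6a over-representation
bias.

**Per-subunit Boltzmann-shift SSI model.** Each incorporated DPP6K
subunit shifts the availability midpoint by −2.3 mV; population curves
are binomial-weighted sums of shifted Boltzmanns, refit with a single
Boltzmann, and the fitted midpoints regress linearly on DPP6K mole
fraction.

**Trace analysis.** Multi-exponential decay fits with the τ-n/W-n/W-ss
convention, mono/bi-exponential recovery fits R(t) = 1 − Σ wᵢ exp(−t/τᵢ),
Boltzmann G–V and SSI fits, the peak-over-area fast-τ estimator,
scaled-null leak subtraction, prepulse-subtraction I_SA isolation,
fractional recovery, and junction-potential correction.

**Synthetic data.** A seeded generator reproduces the statistical
structure of the recordings (bi-exponential decays, two-pulse recovery
families, SSI prepulse families, Markov-scheme decays) from named
fixture presets, so the full pipeline is testable without recordings.

## Worked example

Predict how much fast inactivation can slow when only one DPP6a subunit
remains on a four-site channel (model1), then fit a noisy synthetic
granule-cell decay:

```r
library(isakit)

stoich_predict("model1-4")
#>     n_a   n_K tau_fast_ms fast_amplitude p_open_eq p_inactivated_eq
#> 1     0     4        32.6          0.756     0.244            0.756
#> 2     1     3        11.6          0.502     0.253            0.747
#> 3     2     2         8.7          0.608     0.263            0.737
#> 4     3     1         7            0.671     0.274            0.726
#> 5     4     0         6            0.714     0.286            0.714

tr  <- gen_decay_trace("CG", duration_ms = 1000, noise_sd = 0.01, seed = 42)
fit <- fit_exp_decay(tr, n_components = 2)
tidy(fit)
#>   component tau_ms amplitude weight_pct
#> 1 tau-1       11.0    0.722       72.1
#> 2 tau-2      120.     0.250       24.9
#> 3 steady      NA      0.0299      2.98
```

The prediction table reads: a pure DPP6a channel (4a) inactivates with
τ = 6.0 ms; stripping it to a single DPP6a subunit slows the fast
component to 11.6 ms — the maximal slowing a four-site channel allows.
The fit recovers the granule-cell preset's generating parameters
(τ₁ = 11 ms, τ₂ = 120 ms, W = 72/25/3 %) from 1 % noise.

The SSI mixture experiment shows the linear midpoint shift:

```r
ssi_mix(mole_fractions_K = seq(0, 1, 0.25))$regression
#>   slope intercept r_squared
#> 1 -9.21     -63.3      1.00
```

i.e. about −2.3 mV per DPP6K subunit × 4 sites, with r² ≈ 1.

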