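---
title: "From corticostriatal plasticity to drift-diffusion parameters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From corticostriatal plasticity to drift-diffusion parameters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This package links three levels of description of value-based decision
making: dopamine-modulated plasticity at corticostriatal synapses, spiking
dynamics of the cortico-basal-ganglia-thalamic (CBGT) loop, and the
drift-diffusion model (DDM) of two-alternative choice.  This vignette is the
package's own account of each model, the free parameters and how their
defaults were chosen, the numerical decisions, and what the simulations can
and cannot show.

## 1. The reduced striatal learning network

`run_learning()` simulates two action channels (L and R), each containing a
population of direct-pathway (dMSN) and indirect-pathway (iMSN) medium spiny
neurons modelled as exponential integrate-and-fire units.  Each neuron
receives one cortical "daughter" spike train, thinned from its channel's
oscillatory-Poisson mother train with transfer probability `pD` (dMSNs) or
`pI` (iMSNs); cortex-to-iMSN release exceeds cortex-to-dMSN, so `pD < pI`.

An action is selected when three distinct dMSNs of one channel spike within
a 10 ms window; each iMSN spike in a channel suppresses that channel's most
recent counted dMSN spike.  After a selection, counters reset and cortical
input is silenced for 50 ms.  Reward is Bernoulli (`p_L + p_R = 1`), action
values follow tabular Q-learning, and the phasic dopamine level is the
reward prediction error `DA = r - max(Q_L, Q_R)`, broadcast to every
synapse.  Each corticostriatal synapse carries an eligibility trace built
from nearest-neighbour pair-based STDP (pre-before-post potentiates, the
reverse depresses, exponential decay in between), and weights move by
`gain * DA_eff * e`, clipped to `[0, w_max]`.

Two asymmetries carry the biology:

* dMSN synapses have a larger dopamine gain than iMSN synapses
  (`eta_d > eta_i`), and respond more weakly to dopamine *dips* than bursts
  (`DA_eff = kappa_d * DA` for `DA < 0`, `kappa_d = 0.6`), reflecting
  D1-receptor plasticity that is driven mainly by phasic bursts;
* the iMSN update has opposite sign (bursts depress cortico-iMSN synapses),
  with a small gain, leaving iMSN weights near their initial value with a
  slight downward drift.

Most constants of this sub-model (mother-train rate 500 Hz with 8 Hz
oscillation at depth 0.8, STDP amplitudes 1 / 0.3 with 20 ms windows,
eligibility decay 300 ms, gains 0.4 / 0.05, Q-learning rate 0.02, initial
weight 12 nS) are not fixed by any published description; they are exposed
in `stdp_params()` and their defaults were chosen once so that the model
reproduces its qualitative benchmarks — rising dMSN weights in the
better-rewarded channel, near-equal iMSN weights, concurrent dMSN/iMSN
activity around selections, and a between-channel dMSN weight separation
that grows as the reward probabilities become less similar
(`p_L` from 0.65 to 0.85).  They were not revisited afterwards.  A slow
Q-learning rate matters here: the separation is created during the early
phase in which prediction errors are still large, so the value estimate must
not converge too quickly relative to the 15 s realization.

The learned weight *ratios* `w_D/w_I` motivate the condition table used by
the spiking network (`cbgt_table4()`); the network stage feeds forward the
printed scalings themselves, not freshly learned ratios.  `ratios_to_phi()`
exists for exploratory use.

```{r}
library(cbgtddm)
learn <- run_learning(p_L = 0.85, n_realizations = 8, seed = 1)
print(learn)
```

## 2. The spiking CBGT network

### Neurons

All units are integrate-and-fire-or-burst neurons,

$$C \dot V = -g_L (V - V_L) - g_T\, h\, H(V - V_h)(V - V_T) - I_{syn},$$

with C = 0.5 nF, g~L~ = 25 nS, V~L~ = −70 mV, spike boundary −50 mV, reset
−55 mV.  The T-current inactivation h decays with a 20 ms constant above
V~h~ and recovers toward 1 with a 100 ms constant below it.  Cortex,
striatum, FSIs, GPi and thalamus have g~T~ = 0 (pure leaky
integrate-and-fire); GPe and STN have g~T~ = 0.06 nS.  Two conventions are
worth making explicit: the activation threshold is taken as V~h~ = −60 mV
(the standard value for this model family; a threshold of −0.60 mV would sit
above the spike boundary and permanently disable the current, contradicting
the rebound-bursting role of GPe/STN), and the inactivation decay constant
is stored as a positive magnitude and always applied as a decay.  The
Heaviside gate is closed on the depolarized side (H = 1 at exactly V = V~h~).
No refractory period follows reset; none is specified for this model family,
and the absence is documented rather than guessed.

### Synapses

Currents are receptor-resolved:
$$I_{syn} = g_1 s_1 (V - V_E) + \frac{g_2 s_2 (V - V_E)}{1 + e^{-0.062 V}/3.57} + g_3 s_3 (V - V_I),$$
with AMPA/GABA~A~ gating incrementing by one per presynaptic spike and
decaying with 2 / 5 ms constants, and NMDA gating incrementing by
$\alpha(1-s)$ per spike ($\alpha = 0.63$, decay 100 ms).  Transmission delay
is 0.2 ms, rounded up to a whole number of integration steps (four steps at
the default dt).

Gating is pooled per afferent population, receptor and target neuron rather
than per synapse.  For the linear AMPA/GABA kinetics the pooled
conductance-weighted sum is exactly equivalent to per-synapse gating.  The
saturating NMDA gate is pooled with a capacity equal to the target's
in-degree for that projection (`S += alpha (1 - S/n_in)` per arriving
spike), which is exact when the per-synapse gates are statistically
homogeneous; a plain 0–1 pooled gate would saturate a whole afferent
population at the level of one synapse and break the conductance scale the
connectivity table was tuned for.

### Architecture and wiring

`build_cbgt_network()` realizes the connectivity table (`cbgt_table3()`)
with independent Bernoulli(P) draws per cell pair: focal rows wire only
within an action channel, diffuse rows wire all channel combinations, rows
with AMPA and NMDA components share one wiring draw, and autapses are
excluded.  Population sizes are 270 cortical cells per channel, 250 cortical
interneurons, 100 dMSNs, 100 iMSNs and 100 thalamic cells per channel, 100
FSIs, and 1000 GPe and STN cells per channel with 100 GPi cells per channel.
The hyperdirect pathway is represented as background drive to the STN rather
than explicit cortico-subthalamic wiring.  `sample_subject_network()`
implements the robustness protocol: every table row's efficacy resampled as
N(g, 0.05 g) (non-positive draws rejected), with the row weight
$\omega = P \cdot g$.

### Background and stimulus drives — the calibrated free parameters

The model's synaptic current includes background input from sources outside
the six modelled regions.  No rates are published for these drives, so they
are the network's honest free parameters: independent Poisson trains per
neuron through AMPA receptors, one (rate, unitary conductance) pair per
population, exposed in `cbgt_config()` and fitted once with the iterative
helper `calibrate_background()` plus hand refinement.  The calibration
targets were qualitative and fixed in advance: low tonic rates in cortex
(~5–8 Hz) and striatum (<1 Hz), moderate FSI activity, high tonic GPe
(~75–80 Hz) and GPi (~110–120 Hz) firing, thalamus well below the 30 Hz
decision threshold (~1–2 Hz), and — once the per-trial protocol was in
place — mean choice accuracies and correct-choice reaction times in the
three reward conditions near their published values.  The calibrated
defaults place most of the striatal noise in large unitary background events
(12.5 nS at ~280 Hz), which keeps medium spiny neurons in a fluctuation
driven regime: their response to the small corticostriatal efficacy
differences (±1% to ±5.5% across conditions) is then strongly supralinear,
which is what lets those differences decide choices at the observed rates.

The background model has one slow component: on each trial the cortical
background rate is scaled by a multiplicative factor drawn from a truncated
normal with cv = 0.04 (`bg_trial_cv`), representing trial-to-trial
fluctuations of cortical excitability.  This component is channel-symmetric,
so it cannot bias the choice; what it does is spread decision times across
trials.  Without it the network's threshold crossings are far more
punctual than empirical RT distributions, and a DDM fitted to such data
compensates with an implausibly small boundary separation and inflated
drift.  With it, the RT means, dispersion and positive skew — and
consequently the fitted drift-rate scale — match the published behaviour.

Two deliberate conventions: the unitary background conductances are *not*
varied across reward conditions or subjects (they are part of the model
definition), and the same calibration is used for every wiring seed — the
behavioural statistics are self-averaging at these population sizes.

The per-trial stimulus draws one rate from a truncated normal (mean 2.5 Hz,
sd 0.06, bounds [2.4, 2.6] Hz) and applies it *identically* to the L and R
cortical populations as independent Poisson trains of rate
`stimulus x stim_fan_in` per neuron (fan-in 250, 1.4 nS events), ramping
linearly over the first 200 ms after stimulus onset.  The ramp realizes the
gradually increasing cortical rates of the trial protocol; its duration and
the plateau strength were calibrated together with the backgrounds.  With
the plateau slightly below the deterministic decision level, threshold
crossings are fluctuation-driven, which produces the right-skewed RT
distributions expected of accumulation-to-bound behaviour.

### Trial protocol and readout

A trial lasts up to `t_max_ms` (default 1800 ms) with stimulus onset at
200 ms.  The decision readout is the population firing rate of each
thalamic channel in a sliding 10 ms window advanced every 1 ms; the first
channel to reach 30 Hz after onset is selected and the RT is the absolute
crossing time within the trial (so the published ~460–480 ms means include
the 200 ms onset).  If both channels cross within the same millisecond the
higher rate wins and exact ties break at random; trials without a crossing
time out as undecided and are excluded from RT summaries.  The trial window
is longer than the nominal 1 s protocol so that the slow tail of the RT
distribution is observed rather than censored; decided trials end at the
crossing, so the extension costs little compute.

### What passing behavioural checks do and do not show

The behavioural acceptance bands (accuracy ≈ 64 / 85 / 100 %, correct-choice
mean RTs ≈ 477 / 460 ms with positive skew) are reproduced at 200 trials per
condition.  Because the background drives are calibrated free parameters,
agreement demonstrates that the published connectivity and weight-scaling
tables *can* generate the published behaviour under a plausible operating
point — not that this operating point is unique.  Quantities downstream of
behaviour (striatal summary statistics, DDM parameter gradients, model
ranking) are genuine model outputs, not calibration targets.

## 3. Striatal summary statistics

For every decided trial, `striatal_summaries()` integrates each striatal
population's firing rate (trapezoid on the 1 ms grid) from stimulus onset to
that trial's RT, min–max normalizes the four raw AUC components *pooled
across all trials of all conditions*, and composes the four regressors:
D~L~−D~R~, D~L~−I~L~, I~L~−I~R~, and I~all~ (the mean of the two normalized
iMSN components).  Normalization is applied per population before
differencing; the alternative (difference then normalize) changes the
support of the regressors and is not used.  Undecided trials are dropped
with a log message.  `regress_behavior()` fits the descriptive regressions
(logistic choice on the direct-pathway summaries; linear RT on the
indirect-pathway summaries, correct choices only) through `glm`/`lm`, with a
small ridge-penalized fallback when the logistic fit is separated.

## 4. The drift-diffusion stage

### Likelihood

The DDM likelihood uses the closed-form series for the Wiener first-passage
density with absorbing boundaries at 0 and `a`, start point `z = z_rel * a`,
drift `v`, non-decision time `tr`, and diffusion coefficient fixed at
σ = 1 (the scale on which all drift and boundary values are quoted; σ is a
pure scaling degeneracy).  Two equivalent expansions exist; `dwfpt()`
evaluates whichever needs fewer terms at the requested error bound
(10^−7^ by default), erroring rather than truncating silently if the bound
cannot be met.  The upper-boundary density is the reflection z → a−z,
v → −v, and the L (higher-reward) response maps to the upper boundary.
Inter-trial variability parameters are deliberately absent — the process
model fitted here has none.

### Models

`ddm_model()` spans the whole model space: parameters shared across
conditions, free per condition, or driven by a trialwise neural regressor
with a shared intercept and one slope per condition
(`p_t = beta0 + beta_j X_t`).  `ddm_regression_models()` enumerates the
twelve (v, a) and twelve (v, z) regression models in their conventional
order; model III couples v to D~L~−D~R~ and a to I~all~.

### Sampling

`ddm_fit()` draws 2000 Metropolis-within-Gibbs samples with the first 1200
discarded, adapting per-parameter Gaussian proposal scales toward a 0.44
acceptance rate during burn-in only.  Priors are weakly informative:
N(0, 5) for drift-like quantities and slopes, half-normal(5) for boundary
like quantities, uniform for the relative start point, truncated
N(0.3, 0.25) for the non-decision time; parameter vectors implying a
non-positive boundary, a start point outside (0, 1), or `rt <= tr` on any
trial have zero prior mass or likelihood.  Underflowing (but structurally
admissible) trial densities are floored at a configurable log-floor.
Chains are seed-deterministic; acceptance rates outside [0.1, 0.9] after
adaptation raise a warning, and lag-1 autocorrelations are reported by
`summary()`.

Hierarchical fits give every non-slope parameter subject-level copies under
group-level normal priors whose mean (conjugate update) and spread
(half-normal prior, Metropolis on the log scale) are sampled; regression
slopes are fixed effects shared across subjects.  The group-sd prior is a
half-normal(2.5), matching the scale of plausible between-subject spread.

### Model comparison

`compute_dic()` uses DIC = D(θ̄) + 2 p~D~ with
p~D~ = mean deviance − deviance at the posterior mean; a negative p~D~ is
reported, never clamped.  `stepwise_search()` runs the three-stage forward
procedure: null plus four single-free-parameter models, one added parameter
for the stage-1 winner, then the regression models built on the two best
dual models.  Because DIC *values* depend on the data realization and the
sampler, all comparisons downstream are made at the rank/ordering level
(|ΔDIC| ≥ 10 as the conventional strong-evidence margin), never at the
level of reproducing printed DIC numbers.

### Synthetic data

`generate_dataset()` and `generate_subjects()` emit choice/RT tables with
trialwise regressors and known ground truth, emulating only the statistical
structure the fitting stage assumes: per-condition Wiener data with
regressors drawn from Beta distributions (bounded in [0, 1] like the
normalized striatal summaries) coupling linearly to drift and boundary.
Default condition means mirror the fitted values of the best regression
model (drift about 1.4 / 3.6 / 5.1, boundary about 0.93 / 1.03 / 1.02), with
distinct condition profiles for the decoy regressors.  The generators power
the parameter-recovery, shrinkage, and model-selection-recovery test suites
without any spiking simulation.

## 5. Numerical choices

* **Integrator**: forward Euler at dt = 0.05 ms for the network membrane
  equations (stiff conductance transients are bounded; the dt-halving
  property test bounds the discretization error), exact exponential factors
  for all gating and inactivation decays, and Euler at the printed
  dt = 0.01 ms for the learning network.  A dt-halving convergence test and
  a closed-form leak check guard both.
* **First-passage simulation**: Euler–Maruyama at dt = 10^−4^ s.  The
  discrete scheme under-detects boundary crossings; where simulated paths
  serve as the oracle against the analytic density, the comparison applies
  the standard continuity correction (boundaries shifted outward by
  0.5826 σ √dt).
* **Poisson drives** are generated by exponential waiting times from R's
  RNG, so every trial is reproducible from its integer seed; experiment
  level seeds derive per-trial seeds, and identical (configuration, seed)
  pairs give bit-identical trial tables.
* **Problem sizes** in the shipped test-suite: 200 trials per condition at
  full population size for the behavioural checks, 300 trials per condition
  for the model-selection recovery, 2000 trials for flat parameter
  recovery, 15 subjects x 200 trials per condition for the hierarchical
  recovery, 10^6^ paths for the Monte-Carlo density check, and 7–8
  realizations of 15 s for the learning benchmarks.  These match the
  published designs where one exists (subjects, trials per condition,
  realizations) and otherwise are the package's own choice of scale.

## 6. Known limitations

* The background drives are under-determined by the published material;
  different operating points could produce similar behaviour.  All of them
  are exposed in `cbgt_config()` and the calibration helper is exported.
* The learning model's unpublished constants are non-canonical; only its
  qualitative benchmarks are asserted.
* The pooled NMDA gate is exact only for homogeneous afferents; projections
  with strongly heterogeneous per-synapse rates would need per-synapse
  state.
* Rate-trace storage is in-memory (nested lists of per-trial matrices) with
  CSV writers; at 2500 trials per condition a disk-backed store would be
  preferable.
* The DDM stage excludes inter-trial variability parameters and collapsing
  bounds by design; fits to data generated by such processes will absorb
  their effects into the base parameters.
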