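# cbgtddm

Multi-level modelling of reward-guided decision making in R: from
dopamine-modulated plasticity at corticostriatal synapses, through a spiking
cortico-basal-ganglia-thalamic (CBGT) network that generates choices and
response times, to hierarchical drift-diffusion-model (DDM) fits of the
simulated behaviour.

## The scientific problem

Cortico-basal-ganglia-thalamic circuits implement action selection: cortical
evidence excites direct-pathway striatal neurons (dMSNs, which disinhibit
the thalamus via GPi) and indirect-pathway neurons (iMSNs, which oppose
selection via GPe/STN).  Reward-driven dopamine signals re-weight the
corticostriatal synapses of competing action channels, biasing this
competition.  At the algorithmic level the same behaviour is captured by the
drift-diffusion model,

    d theta = v dt + sigma dW,   theta(t <= tr) = z a,

with drift rate `v`, boundary separation `a`, relative start point `z`, and
non-decision time `tr`; choices and RTs are first passages through the
boundaries at `0` and `a`.  The package makes the mapping between these
levels computable:

1. **`run_learning()`** — a reduced two-channel striatal network with
   spike-timing-dependent plasticity gated by eligibility traces and a
   phasic dopamine signal proportional to the reward prediction error
   `r - max(Q_L, Q_R)` (Q-learning).  It shows how unequal reward
   probabilities drive apart the dMSN/iMSN weight ratios of the two
   channels.
2. **`build_cbgt_network()` / `run_experiment()`** — a six-region spiking
   network (cortex, striatum, GPe, STN, GPi, thalamus; ~5700
   integrate-and-fire-or-burst neurons) wired from a published connectivity
   table, with corticostriatal weights scaled per reward condition
   (`cbgt_table4()`).  A trial applies identical ramping Poisson input to
   both cortical channels; the first thalamic population whose firing rate
   reaches 30 Hz selects the action and sets the RT.
3. **`striatal_summaries()`** — trialwise area-under-the-curve summaries of
   striatal activity (D_L−D_R, D_L−I_L, I_L−I_R, I_all), min-max normalized
   across all trials, used as neural regressors.
4. **`ddm_fit()` / `stepwise_search()`** — Wiener first-passage-time
   likelihood (`dwfpt()`), adaptive Metropolis-within-Gibbs MCMC (2000
   samples, 1200 burn-in), DIC model comparison, hierarchical (multi
   subject) variants, and the three-stage forward model search over
   condition-free and neural-regressor DDMs.

See the methods vignette (`vignettes/cbgt-ddm-methods.Rmd`) for the models,
parameter conventions, and numerical decisions.

## Worked example

Simulate a reduced batch of decision trials in the high reward-probability
condition and fit a drift model (a full-scale batch uses
`cbgt_config()` defaults and 200+ trials per condition; this small example
runs in about a minute):

```r
library(cbgtddm)

net <- build_cbgt_network(cbgt_config(), seed = 7)
ex  <- run_experiment(net, conditions = c("low", "high"), n_trials = 20,
                      seed = 1)
summarize_behavior(ex, n_boot = 500)
#>   condition  n n_decided acc_pct acc_lo acc_hi mean_rt_ms rt_lo rt_hi rt_skew
#> 1       low 20        20      70  47.38     90      427.4 382.3 479.7   1.469
#> 2      high 20        20      95  85.00    100      499.3 389.2 649.3   3.078
```

Accuracy is the percentage of trials choosing the higher-reward (L) action;
RTs are absolute threshold-crossing times within the trial (stimulus onset
at 200 ms) for correct choices, with bootstrap 95% intervals.  The high
condition approaches saturation while the low condition stays near 70% at
this small trial count — at 20 trials the RT means are still noisy, but the
choice asymmetry is already the behavioural signature the DDM stage
decomposes:

```r
behavior <- experiment_to_behavior(ex)
fit <- ddm_fit(behavior, ddm_model(free = "v"), n_samples = 800, burn = 500,
               seed = 2)
posterior_to_condition_params(fit)$v$summary
#>      condition mean    sd
#> high      high 2.11 0.481
#> low        low 1.39 0.501
```

The posterior-mean drift rate rises with reward probability: stronger
corticostriatal imbalance maps onto faster evidence accumulation toward the
correct boundary.

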