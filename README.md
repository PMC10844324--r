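# bcibind

Generative observer models of **temporal (intentional) binding** — the
subjective compression of the interval between a voluntary action and its
sensory outcome — with simulation, Monte-Carlo maximum-likelihood fitting,
AIC model comparison, and parameter/model-recovery pipelines.

## Who this is for

Researchers in computational cognitive neuroscience who measure binding with
Libet-clock–style timing reports and want to go beyond mean shifts: fit
trial-level models of *how* reports arise, compare causal-inference accounts
against non-Bayesian alternatives, and check — before interpreting fitted
parameters — that those parameters are identifiable under their design.

## The model space

Percepts of action and outcome are Gaussian around the physical event times
(per-observer bias `b` and noise `σ`, estimated from baseline blocks). Under
a causal scenario, a Gaussian coupling prior `N(μ_AO, σ_AO²)` over the
action–outcome interval shrinks the percepts toward the expected gap:

    t̂_A,ξ=1 = τ_A + (σ_A²/σ_tot²) (τ_O − τ_A − μ_AO)
    t̂_O,ξ=1 = τ_O − (σ_O²/σ_tot²) (τ_O − τ_A − μ_AO),   σ_tot² = σ_A² + σ_O² + σ_AO²

Twelve candidate models differ in how (and whether) the causal posterior is
used: Bayesian causal inference with **j**oint-**p**osterior,
**m**odel-**s**election, **m**odel-**a**veraging or
**p**robability-**m**atching strategies, each under a **u**nity **p**rior
(`μ_AO = 0`) or free **c**oupling **p**rior (`JPup … PMcp`); mandatory
integration (`MIup`, `MIcp`, i.e. classical MLE fusion); a fixed temporal
criterion (`FC`, average when `τ_O − τ_A ≤ φ`); false reports (`FR`, swap
events with probability `P_fr`); plus a parameter-free null model. Fitting
maximises a simulated (kernel-density) trial likelihood over the shared
bounds and compares models by `AIC = 2k − 2 log L`.

## Worked example

```r
library(bcibind)

# one synthetic observer: probability-matching with a coupling prior
trials <- simulate_observer("PMcp", list(p_causal = 0.7, mu_ao = 100),
                            seed = 1)
binding_indices(trials)
#>   observer_id t_ao action_shift outcome_shift compression
#> 1           1    0   -18.843932     -1.338031 -17.5059008
#> 2           1  250    -2.079328    -40.540481  38.4611535
#> 3           1  500    -5.716009     -6.474137   0.7581277

cfg <- fit_config(n_mc = 20000, seed = 2)
fits <- fit_models(c("PMcp", "MIcp", "FC", "NULL"), trials, cfg)
as.data.frame(fits)
#>   model p_causal mu_ao   phi p_fr log_lik k  aic
#> 1  PMcp   0.7809 143.9    NA   NA   -2698 2 5400
#> 2  MIcp       NA 281.2    NA   NA   -4516 1 9034
#> 3    FC       NA    NA 44.71   NA   -2739 1 5481
#> 4  NULL       NA    NA    NA   NA   -2734 0 5469
```

Read: this observer shows *repulsion* at the 0 ms interval (compression
−17.5 ms — the coupling prior of 100 ms exceeds the perceived gap) and
compression at 250 ms (+38.5 ms). The generating model wins the AIC
comparison by ~70 points over the best alternative and recovers its
parameters near the truth (`p_causal` 0.78 vs 0.70, `μ_AO` 144 vs 100 ms
from 480 trials); mandatory integration, which cannot turn integration off,
fails badly.

Identifiability pipelines:

```r
rec <- run_parameter_recovery(n_observers = 20, cfg = fit_config(n_mc = 20000),
                              seed = 1)    # ~4 min, all 11 recoverable models
summary(rec)                               # Pearson r per model-parameter pair
mat <- run_model_recovery(rec, max_observers = 5)  # 12 x 12 confusion matrix
```

A thin command-line wrapper (`inst/scripts/binding-cli.R`) exposes
`simulate`, `fit`, `recover` and `summarize` subcommands over the same
functions.

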