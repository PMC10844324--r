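---
title: "Observer models of temporal binding: generative assumptions, fitting and identifiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer models of temporal binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcibind)
```

## The phenomenon and the modeling question

When a voluntary action (a keypress) causes a sensory outcome (a tone),
observers report the action as later and the outcome as earlier than they do
when either event occurs alone — the perceived action–outcome interval is
compressed. This *temporal (intentional) binding* effect is usually measured
with the Libet clock: observers report event timing from the position of a
rotating clock hand, and the estimation error (reported minus physical time,
in ms) is compared between *baseline* blocks (single events) and *operant*
blocks (action causes outcome after 0, 250 or 500 ms).

`bcibind` implements a family of generative observer models that each
predict, trial by trial, how operant reports arise from noisy percepts, and
the machinery to simulate, fit and compare them. The scientific question the
model comparison addresses is *whether and how observers' causal beliefs
shape their timing reports*: full Bayesian causal inference, mandatory cue
fusion, a hard temporal criterion, or mere response errors.

## The generative model

All times are in ms with the physical action time at 0, so the physical
outcome time equals the interval $t_{AO}$. Percepts are Gaussian around the
physical times,

$$\tau_A \sim N(b_A, \sigma_A^2), \qquad
  \tau_O \sim N(t_{AO} + b_O, \sigma_O^2),$$

where $b$ and $\sigma$ are per-observer report bias and sensory noise. In
baseline blocks there is nothing to integrate and the report is the percept
itself; the baseline error distributions therefore *are* the sensory
distributions, which is why every model takes $(b_A,\sigma_A,b_O,\sigma_O)$
as fixed parameters estimated from each observer's own baseline cells
(`estimate_baseline_params()`, sample mean and SD with the $n-1$
denominator).

Under the causal scenario ($\xi = 1$) a Gaussian *coupling prior*
$N(\mu_{AO}, \sigma_{AO}^2)$ over the interval pulls the two percepts toward
the expected gap; the MAP estimates are

$$\hat t_{A,1} = \tau_A + \frac{\sigma_A^2}{\sigma_{tot}^2}
   (\tau_O - \tau_A - \mu_{AO}), \qquad
  \hat t_{O,1} = \tau_O - \frac{\sigma_O^2}{\sigma_{tot}^2}
   (\tau_O - \tau_A - \mu_{AO}),$$

with $\sigma_{tot}^2 = \sigma_A^2 + \sigma_O^2 + \sigma_{AO}^2$. Under the
acausal scenario ($\xi = 0$, uniform interval prior over a range $T$) the
estimates are the raw percepts. Because the shift is signed, the same
machinery predicts *compression* when the perceived gap exceeds the prior
and *repulsion* when it falls short — the key qualitative signature that
separates coupling-prior observers from unity-prior ones
($\mu_{AO} \equiv 0$).

Two constants are shared by all observers and never fitted:
$\sigma_{AO} = 10$ ms (the coupling prior is a strong, narrow expectation)
and $T = 250$ ms (normalisation range of the acausal prior). The interval
variance could not be separated from the causal prior in this design, which
is why it stays fixed rather than free.

### The twelve candidate models

The causal posterior can be used in four ways, and each strategy is crossed
with the two temporal priors (unity `up`, coupling `cp`):

* **JP** (joint posterior): compare the *peak heights* of the causal and
  acausal joint posteriors; the ratio has the closed form
  $r = \frac{p}{1-p}\,\frac{T}{\sqrt{2\pi}\,\sigma_{AO}}
  \exp\!\big(-\tfrac{(\tau_O-\tau_A-\mu_{AO})^2}{2\sigma_{tot}^2}\big)$,
  and the causal estimates are reported when $r > 1$.
* **MS** (model selection): commit to the scenario whose *marginal*
  posterior $P(\xi = 1 \mid \tau_A, \tau_O)$ exceeds 0.5.
* **MA** (model averaging): report the posterior-weighted average of the two
  scenario estimates.
* **PM** (probability matching): sample the scenario with probability equal
  to its posterior, once per trial.

The marginal posterior differs from the peak-ratio rule only in its
prefactor ($\sigma_{tot}$ in place of $\sigma_{AO}$) — one of the few places
where an implementation can silently go wrong, so both quantities are tested
against brute-force grid integration/maximisation of the joint density.

Four further models complete the space: **MI** (mandatory integration,
$P(\xi=1)$ fixed at 1 — classical maximum-likelihood cue fusion; the four
strategies coincide, so only the two priors remain, and MIup has *no* free
parameters), **FC** (fixed criterion: average the two percepts whenever the
signed gap $\tau_O - \tau_A \le \phi$), **FR** (false report: with
probability $P_{fr}$ report the other event's percept), and the **null**
model (operant reports are baseline reports; no binding).

Free parameters and their bounds — also the uniform sampling ranges of the
recovery analyses — are $P(\xi=1) \in [0,1]$, $\mu_{AO} \in [0,500]$ ms,
$\phi \in [0,1000]$ ms, $P_{fr} \in [0,1]$.

Three readings deserve a note. The false-report decision is implemented as
"swap when the trial's uniform draw falls below $P_{fr}$", which is the only
reading under which $P_{fr}=0$ means error-free reporting. The
model-selection rule compares the causal marginal posterior against 0.5 for
both target events. And the fixed-criterion comparison is deliberately
*signed*: a negative perceived gap always integrates.

## The synthetic experiment

`simulate_observer()` reproduces the design of the reference experiment: two
baseline cells (keypress, tone) and operant action/outcome reports at
intervals 0/250/500 ms, 60 trials per cell — 8 cells, 480 trials per
observer — with 76 observers at full scale. Baseline trials report raw
percepts; operant trials pass fresh percepts through the generating model's
decision rule. One uniform draw per trial drives every stochastic branch
(the probability-matching scenario choice or the false-report swap), the
minimal reading of "sampled on each trial".

Default sensory parameters are the observed group baselines
($b_A = -52.22$, $\sigma_A = 61.56$, $b_O = 18.27$, $\sigma_O = 61.56$ ms;
the two printed SDs are identical in the source and are kept as printed).
Per-observer parameter jitter is deliberately off by default — recovery
analyses are run at fixed baselines — but any `observer_params()` can be
passed in. Seeding is hierarchical (`derive_seed()`): master seed →
per-observer streams → per-cell draws, so any observer regenerates
independently.

What the simulator does *not* emulate: clock rendering and angle-to-ms
conversion (the package works directly in ms error space), keypress
latencies, practice trials, attention lapses, and any trial-order or
learning effects. Passing recovery tests therefore shows identifiability
*under the model family's own assumptions*, not that real observers satisfy
them.

The baseline tone's random onset is not modelled: the generative equations
never use it, and all binding indices are invariant to a common time offset,
so baseline-outcome trials are recorded in the same frame as action trials
(`t_ao = 0`, error = report).

## Monte-Carlo likelihood and fitting

Most models' operant response densities have no closed form, so
`mc_likelihood()` simulates the predicted response distribution per
condition cell — `n_mc` percept pairs pushed through the decision rule — and
scores each observed report under a Gaussian kernel density estimate
(Silverman's bandwidth) of the simulated sample. Numerical choices that
matter:

* **Stratified base draws.** The percept/uniform draws use Latin-hypercube
  stratification (exact marginals, sharply reduced Monte-Carlo variance).
  For models whose responses are linear in the percepts (null, MI) the
  simulated density then matches the exact Gaussian to within a few percent
  at `n_mc = 1e5` even two SDs from the mean, which the tests verify.
* **Common random numbers.** One set of base draws per fit, reused by every
  optimizer evaluation and every candidate parameter value, makes the
  objective a deterministic function of the parameters — two identical calls
  to `fit_model()` return identical results.
* **KDE evaluation** bins the simulated sample at 1 ms and sums the exact
  kernel over a ±6-bandwidth window; binning resolution is far below any
  realistic bandwidth (≈ 5–40 ms). A fixed-width histogram estimator
  (5 ms bins) is available via `fit_config(density = "histogram")`.
* **Likelihood floor** of 1e-10 per trial keeps the objective finite for
  reports far outside the predicted mass; it is orders of magnitude below
  any plausible density (baseline densities peak near 6e-3).
* **Degenerate inputs.** Baseline cells with zero error spread are rejected
  (the sensory SD must be positive); a near-constant simulated sample falls
  back to a minimal bandwidth rather than failing.

Baseline trials enter the likelihood in closed form as a model-independent
constant; they fix the sensory parameters but cannot distinguish models.
With several observers in one table `fit_model()` shares the free
parameters across observers (group-level fit) while keeping each observer's
sensory parameters individual.

**Optimisation.** The free-parameter spaces are 0–2 dimensional boxes, so
the maximiser is a deterministic successive grid refinement: a coarse grid
over the full box (17 points in 1-D, 9² in 2-D), then two progressively
finer grids centred on the running optimum (resolution ≈ range/200 in 1-D,
range/100 in 2-D — comfortably below the Monte-Carlo noise floor of the
objective). Any bounded global method would do; this one is exactly
reproducible, needs no RNG, and its cost (35 / 131 evaluations) is what
makes the full recovery pipelines tractable on one CPU. Ties resolve to the
lowest parameter value, deterministically. Flat likelihood regions do occur
— e.g. a joint-posterior observer with $P(\xi=1)$ below the point where the
peak ratio can ever exceed 1 produces data indistinguishable from the null
model — and then the recovered value sits at the lower edge of the flat
region; this is a property of the models, not of the optimizer.

**Model comparison** uses the AIC, $2k - 2\log L$, with $k$ = number of
free parameters (0–2). Published group-level tables for this paradigm count
one additional parameter per model; `fit_config(aic_k_offset = 1)`
reproduces that counting (the arithmetic is unit-tested against the printed
probability-matching and null rows). Since every model of one comparison
shares the offset, rankings are unaffected.

## Recovery analyses and chosen problem sizes

`run_parameter_recovery()` draws ground-truth parameters uniformly from the
bounds, simulates each ideal observer's full 480-trial session, refits the
generating model, and reports Pearson correlations between true and
recovered values per model-parameter pair. The recovery refits condition on
the *known* generating sensory parameters rather than re-estimating them
from each simulated observer's baselines (`fit_model(..., params = )`).
This isolates the free parameters under study and matters more than it may
seem: with the default equal sensory noises, the mandatory-integration
weights $\sigma_A^2/\sigma_{tot}^2$ are hypersensitive to the estimated
noise ratio, and a chance imbalance in a 60-trial baseline shifts the
predicted operant means by tens of ms — enough to make a plain-averaging
fixed-criterion model beat the true mandatory-integration model on its own
data. Fits to *real* data, where the truth is unknown, always estimate the
sensory parameters from the observer's baselines (the default). `run_model_recovery()` then
refits *all twelve* candidates to every simulated dataset and tabulates
best-fit proportions per generating model (minimum AIC; ties break toward
fewer parameters, then alphabetically). The unity-prior mandatory
integration model has no parameters to recover, so its generator column is
simulated on demand inside the model-recovery step; correlations are
averaged over the 15 model-parameter pairs the other 11 models define.

The package's desk-scale defaults — 20 observers per model and
`n_mc = 20,000` for parameter recovery; the first 5 observers per generator
and `n_mc = 10,000` for the 12 × 12 model-recovery refits (720 fits) — were
chosen once so that the full identifiability suite runs in minutes on a
single core while staying in the regime where the full-scale analyses (76
observers, `n_mc = 1e5`) report mean recovery correlations around 0.74.
Expected patterns, all reproduced by the test suite: near-perfect recovery
for MIcp and FC, good recovery for most Bayesian variants, visibly weaker
recovery for model-selection observers (their hard 0.5 threshold makes wide
parameter regions behaviourally equivalent), and a confusion matrix with a
dominant diagonal for the non-Bayesian generators but substantial
joint-posterior ↔ model-selection confusion within the Bayesian family —
both rules reduce to "integrate when the gap is below a threshold", and
differ only in where that threshold sits. At the default *equal* sensory
noises this threshold equivalence extends to the fixed-criterion model: the
causal MAP weights are then ≈ 1/2, so a joint-posterior observer is nearly
a fixed-criterion averager with $\phi$ tied to $P(\xi=1)$, and best-fit
identity among {JP, MS, FC} is often decided by AIC margins under 2.
Generators drawn with a causal prior too weak ever to integrate produce
literally null data, which no refit can attribute. Both effects are
inherent limits of the design, not fitting failures.

## Behavioral indices

`estimation_errors()` gives per-cell error summaries and
`binding_indices()` the classic derived measures per observer × interval:
action shift (operant − baseline mean error), outcome shift, and their
difference, the *compression* (positive exactly when the perceived interval
contracted; the outcome shift enters with its sign, so overestimated actions
and underestimated outcomes add up). Monotone growth of compression with
interval length holds for always-integrating unity observers; for causal
inference observers compression can *fall* again at long intervals as
integration shuts down — that non-monotonicity is a model prediction, not a
bug, and the tests only assert monotonicity in the mandatory-integration
limit.

## Known limitations

* The temporal prior is symmetric Gaussian; asymmetric (log-normal/gamma)
  priors that forbid perceived order reversals are out of scope, as is
  fitting $\sigma_{AO}$.
* Inferential statistics on behavioral data (ANOVAs, pairwise tests) are
  deliberately excluded; the metrics module stops at descriptive indices.
* Real datasets are supported through the CSV trial-table interface
  (`read_trials()`), but reproducing published group-level fits requires the
  original data and full-scale computation; nothing in the test suite
  depends on it.
* Likelihoods for strongly bimodal response distributions (e.g. a
  fixed-criterion observer with $\phi$ in the middle of a condition's gap
  distribution) inherit the usual KDE smoothing bias at the mode boundary;
  at the default bandwidths this is far below the Monte-Carlo noise of the
  fit.

## A worked example

```{r example, eval = FALSE}
# simulate a probability-matching observer with a coupling prior
trials <- simulate_observer("PMcp", list(p_causal = 0.7, mu_ao = 100),
                            seed = 1)
binding_indices(trials)

# refit the generating model and compare against the null account
cfg <- fit_config(n_mc = 20000, seed = 2)
fits <- fit_models(c("PMcp", "MIcp", "FC", "NULL"), trials, cfg)
as.data.frame(fits)

# identifiability at reduced scale
rec <- run_parameter_recovery(c("PMcp", "FC"), n_observers = 5,
                              cfg = cfg, seed = 3)
summary(rec)
```
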