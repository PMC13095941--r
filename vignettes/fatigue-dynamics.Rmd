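---
title: "Modelling trial-by-trial dynamics of fatigue and effort perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-by-trial dynamics of fatigue and effort perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguedyn)
```

## The task and the data

`fatiguedyn` models rating data from a grip-force task: 120 trials, each
either a *work* trial — squeeze a dynamometer to 30%, 39% or 48% of one's
maximum voluntary contraction (MVC) for at least 3 s of a 5-s window — or
a matched 5-s *rest* trial, each paired with a reward of 6, 8 or 10
credits. The 12 effort-by-reward combinations are counterbalanced in
blocks of 12 (`trial_sequence()`), and after every trial the participant
rates either how hard the trial felt (0–20, integer steps) or how tired
they feel (0–100, integer steps).

The model's exertion input is not the *requested* effort level but the
force actually produced: the area under the force–time trace
(`force_auc()`, trapezoidal rule), normalized by that participant's
maximum across all their trials (`normalize_auc()`) and multiplied by 10,
giving `E` in [0, 10]. Success on a work trial requires a cumulative 3 s
at or above the target (`judge_success()`); time above threshold is
accumulated over sample intervals whose both endpoints clear the target,
with ties counting as cleared (the on-screen target line is reachable).

## The latent-state model

Momentary fatigue decomposes as

$$F_t = F_{\mathrm{start}} + RF_t + UF_t$$

with both components started at zero and updated once per trial, in the
order unrecoverable-then-recoverable:

$$UF_t = UF_{t-1} + \theta E_t, \qquad
  RF_t = \max\!\big(0,\; RF_{t-1} + \alpha E_t - \delta T_t\big)$$

where $T_t$ is the rest time: 7.5 s on rest trials and 2.5 s on work
trials. Because work trials carry a rest component, the exertion rise and
the rest decline both apply on every trial; they are combined *before*
the floor at zero is enforced. The floor is a model assumption (negative
recoverable fatigue is meaningless), not a fitting device.

Fatigue ratings are read out as $F_t$ itself. Perceived-effort ratings
are read out as

$$PE_t = (\gamma + F_t)\,E_t \quad\text{(multiplicative, default)}
\qquad\text{or}\qquad PE_t = \gamma E_t + F_t \quad\text{(additive)}$$

on work trials and exactly 0 on rest trials, under both combination
rules. $F_{\mathrm{start}}$ is the pre-task baseline rating, replaced by
0.01 when it is zero or was never collected (`resolve_baseline()`), so
the baseline is strictly positive.

The candidate family frees subsets of the parameters: `uf` ($\theta$),
`rf` ($\alpha, \delta$), `rf1` (a single $\alpha$ scaling both the rise
and the decline, $\delta \equiv \alpha$), `uf_rf1` ($\theta, \alpha$
tied), `full` ($\alpha, \delta, \theta$), and — for the effort readout
only — `null` ($\gamma$ alone, no dynamics). Effort-readout models add
$\gamma$ in every case.

Two conventions were genuinely open and are exposed as switches:

* **Readout timing** (`state_timing`). Ratings are given after the
  exertion and outcome of a trial, so the default predicts trial *t*'s
  rating from the state *after* trial *t*'s update (`"post"`); `"pre"`
  uses the state carried into the trial. Only the readout shifts — the
  latent states are identical.
* **Failed work trials** (`include_failed`). The model consumes the force
  actually produced, so failed trials are informative and are fitted by
  default; `include_failed = FALSE` drops them from the residuals.

Predictions are deliberately *not* clamped to the rating scale: ceiling
effects in data are real, and letting the model run past the bound makes
them visible as systematic residuals rather than silently absorbing them.

## Fitting

`fit_fatigue()` minimises the residual sum of squares between observed
and predicted ratings over all rated trials. The objective is evaluated
with a vectorized trajectory: the floored RF recursion is a Lindley
recursion, so with $S_t = \sum_{k\le t}(\alpha E_k - \delta T_k)$,
$RF_t = S_t - \min(0, \min_{k \le t} S_k)$, which removes the R-level
loop and makes the ~40,000 objective evaluations of a multi-start fit
cheap.

Because the surface is only piecewise smooth (every floor event is a
kink) a derivative-free Nelder–Mead simplex is used, restarted from a
full factorial grid of 6 equally spaced initialisations per free
parameter on [0, 1] (endpoints included; 216 starts for the 3-parameter
fatigue `full` model, 1296 for its 4-parameter effort counterpart).
Non-negativity is enforced by a large finite penalty ($10^{12}$,
increasing with the violation) so the simplex is steered back rather than
reparameterized. Each start runs with relative tolerance $10^{-8}$ and
$200 d$ iterations; the best start is then polished once at tolerance
$10^{-12}$ with 5000 iterations, and the final parameters are projected
onto $[0, \infty)$. Equal-RSS starts keep the first in grid order and are
counted in the fit object. The whole procedure is deterministic given the
data.

Fits are scored by $\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2d$ with $n$
the number of fitted trials and $d$ the number of free parameters, and by
$R^2$, the squared Pearson correlation between observed and predicted
ratings. An RSS below $10^{-12}$ (noiseless synthetic data) is floored
there with a warning, since the AIC is undefined at zero; $R^2$ is
reported as `NA` when either side has zero variance. For the `null`
effort model the least-squares weight has the closed form
$\hat\gamma = \sum rE / \sum E^2 - F_{\mathrm{start}}$
(`null_gamma_closed_form()`), kept as an independent check on the
optimizer.

## Group-level comparison

`compare_fatigue_models()` aggregates per-subject fits three ways: summed
AIC, best-fit counts by AIC and by RSS (exact ties go to the
lowest-indexed model and are reported), and random-effects Bayesian model
selection. For the latter, per-subject log model evidences are
approximated by $-\mathrm{AIC}/2$ ("inverted AICs") — an approximation to
the free energy the original variational scheme expects — and the
posterior Dirichlet over population model frequencies is found by
iterating

$$u_{nk} \propto \exp\!\big(\ln p(y_n \mid m_k) + \psi(\alpha_k) -
\psi(\textstyle\sum_j \alpha_j)\big), \qquad
\alpha_k = \alpha_0 + \sum_n u_{nk}$$

to a tolerance of $10^{-6}$ on $\alpha$, with a uniform prior
$\alpha_0 = 1$ and responsibilities computed in log space with per-row
max subtraction (stable for evidence spreads up to ~$10^4$ log-units).
Exceedance probabilities — $P(\text{model } k \text{ is the most
frequent})$ — are estimated by seeded Monte-Carlo sampling from the
Dirichlet via independent Gamma draws ($10^6$ by default, in chunks to
bound memory). For two models the exceedance probability has the closed
form $P(\mathrm{Beta}(\alpha_1, \alpha_2) > 1/2)$, which the test suite
uses as a quadrature oracle against the sampler; the group posterior is
invariant to per-subject constants added to the evidences, which is also
tested.

## The synthetic-cohort generator

`simulate_cohort()` exists so that fitting and comparison can be
exercised end to end with known ground truth. It emulates the task
structure faithfully: the counterbalanced 120-trial sequence shared by
all participants, 5-s force traces built from a ramp–hold–release
template aimed 5% above the target line with Gaussian wobble,
reward-invigorated extra force when the reward is visible before
exertion (absent in the hidden-reward variant of the task), a small rate
of sub-3-s holds that fail the trial, per-participant AUC normalisation,
and integer-quantized, bound-censored ratings with additive Gaussian
noise (default 5% of the scale). Sequence, force and rating noise draw
from separate streams derived from one master seed, so each can be varied
independently and every output is reproducible.

Two generator design choices deserve explanation, because they are about
*identifiability*, not convenience:

* **The recovery-to-exertion ratio.** Without floor contact,
  $F_t = F_{\mathrm{start}} + (\alpha + \theta)\sum E - \delta \sum T$:
  a subject whose recoverable fatigue never drains to zero mid-task lies
  on an exactly flat $(\alpha + \varepsilon, \theta - \varepsilon)$ ridge
  and the two components cannot be separated even from noiseless data —
  a structural property of the model, not a fitting failure. Dividing RF
  by $\alpha$ shows that floor contact depends only on the sequence and
  the ratio $c = \delta/\alpha$ (scaled gains $E - 2.5c$, scaled dips
  $7.5c$); with mean work exertion near 7.5 the drift balance point is
  $c \approx 1.53$. Ground-truth draws therefore use
  $\delta = \alpha \cdot U[1.55, 1.95]$: every subject is mean-reverting,
  RF revisits its floor (separating $\theta$), and longer or harder work
  runs still leave rests only partially depleting RF (separating
  $\delta$ from $\alpha$). An explicit independent `delta` range can be
  supplied to study the non-identifiable regimes deliberately.
* **The canonical sequence.** Because floor contact is a deterministic
  property of (sequence, ratio), the default shared sequence — like the
  one fixed sequence all participants saw in the real task — is a design
  constant (`sequence_seed = 84`), certified by a scan: for every ratio
  in the default band, the scaled RF process floors at least five times
  across the task, including after trial 43.

The remaining default ranges are chosen to produce realistic
trajectories on the 0–100 fatigue scale: $\alpha \sim U[0.3, 0.9]$ (rest
dips of roughly 4–11 rating points, clearly visible against the 5-point
rating noise), $\theta \sim U[0.01, 0.1]$ (an unrecoverable rise of
~6–75 points over the task), integer baselines in 0–20, and ~2% of
ratings at the ceiling — a small saturating proportion, as in real data.
Effort-readout truth uses ~50× smaller latent ranges, since fatigue
multiplies exertion on a 0–20 scale. For exact-recovery studies,
`quantize = FALSE` and `censor = FALSE` disable rounding and bound
censoring, and `noise_sd = 0` removes rating noise; in that configuration
the generating parameters are recovered to ~$10^{-10}$ relative error
with RSS below $10^{-16}$.

What the generator does *not* emulate: rating carry-over inertia (the
scale starts at the previous trial's value and adjustment time is
capped), non-Gaussian or autocorrelated rating noise, force drift with
time-on-task, and any reward effect on the ratings themselves beyond its
effect through force. Passing recovery tests on synthetic cohorts
therefore shows the machinery is correct and the design informative — not
that real ratings obey the model.

## Problem sizes and runtime

The shipped checks use cohorts of 20 subjects (noiseless recovery), 50
subjects (noisy recovery, 5%-of-scale noise), and 40 subjects per
generating model (model recovery across the five fatigue-readout
candidates), each on the canonical 120-trial task — sizes in the range of
the original experiments and comfortably computable in a few minutes on
one CPU thanks to the vectorized trajectory.

## Known limitations

* The additive effort variants retain $PE = 0$ on rest trials; whether
  fatigue should leak into rest-trial effort ratings under the additive
  rule is not decidable from the model definition alone.
* AIC-based evidences are a coarse approximation to marginal likelihoods;
  exceedance probabilities inherit that approximation. Protected
  exceedance probabilities and Bayesian omnibus risk are out of scope.
* With rating noise, $\hat\alpha$ and $\hat\delta$ are mildly biased
  upward (the floor makes the model locally more flexible upward than
  downward); true-vs-recovered correlations are unaffected.
* Subjects generated outside the mean-reverting regime are fit without
  complaint, but their recoverable/unrecoverable split is not trustworthy
  — inspect floor contact (`RF == 0` events in the trajectory) before
  interpreting $\alpha$ vs $\theta$ for any individual.
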