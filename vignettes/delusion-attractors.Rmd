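---
title: "Habits, precision and delusion-like inference: the delusim model"
author: "delusim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habits, precision and delusion-like inference: the delusim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delusim)
```

## The task and the scientific question

delusim simulates a discrete-state active-inference agent performing a
250-trial advisor/card task. On every trial one of two cards (blue/green) is
correct; an advisor — trustworthy or untrustworthy — names a card; the agent
chooses a card and receives feedback. A trustworthy advisor names the correct
card; the realized intention flips away from its schedule on 10% of trials.
Each trial stands alone: the agent has no across-trial model of the advisor,
so any knowledge that persists between trials must flow through two slower
variables — Dirichlet habit counts over its policies, and the precision with
which it selects among them.

The question the simulations address is how a Bayes-rational agent can come
to hold beliefs that are false, held with certainty, and resistant to
counter-evidence — the classical marks of delusion — without any single
"broken" parameter, and why lowering policy precision (the computational
analogue of antidopaminergic medication) can release it.

## The generative model

Within a trial there are three timesteps (start, advice, choice/feedback)
and five hidden-state factors: advisor intention (2), correct card (2), the
agent's card decision (3: null/blue/green), affect (2: calm/angry) and trial
stage (3). Four outcome modalities are observed: advice, feedback, arousal
(when affect is modelled) and a proprioceptive copy of the choice. The joint
state space has 72 configurations.

Likelihoods: advice is a deterministic readout of intention and card at the
advice stage; feedback is believed correct with probability `a` (the
likelihood precision, 0.5–1) when the chosen card matches the correct card;
arousal reads affect deterministically (calm → low). In the true process the
realized feedback is truthful given the choice and the card: the only
outcome noise the agent faces is the 10% intention flip and its own affect
dynamics. We adopted this after finding that independently noisy feedback
(at the 0.9 reliability of the likelihood family) necessarily misleads every
Bayesian observer on the dishonest trials, which is incompatible with the
fully accurate inference profile the precise habit-resistant benchmark agent
must show, and with fewer than half of all swept agents ever making a false
inference.

Policies: four, `{trust, distrust} x {choose blue, choose green}`, spanning
the trial; the card is enacted at the final transition, while trust/distrust
is a *mental* action, revisable until the final timestep. In the agent's
model, trusting maps the advisor to "trustworthy" deterministically (and
conversely), so beliefs about the advisor ride on beliefs about which policy
is in play. With affect enabled, trusting makes calm twice as likely as
angry, and distrusting the reverse, at every within-trial transition.

Preferences (log scale): feedback `[3, -3, 0]` over correct/incorrect/null —
'correct' expected over 'incorrect' by exp(6) — and arousal `[c, -c]`
(mood): negative `c` means high arousal is expected. Initial-state priors
are uniform over intention, card and affect.

## Inference and policy selection

Per policy, the within-trial model is a three-step hidden Markov chain over
the 72-state joint, so `infer_states()` computes posteriors by exact belief
propagation (one forward–backward sweep reaches the free-energy minimum; the
sweep loop and its 1/128-nat tolerance exist only as a guard). The policy's
free energy `F` is its negative log evidence. Expected free energy `G`
scores each policy's not-yet-observed outcomes as risk plus ambiguity
(equivalently: minus information gain minus expected log-preference); at the
final timestep `G = 0`. We considered and rejected evaluating `G` over the
current timestep's posterior-predictive outcomes: the exp(6) preference then
leaks an "optimism" term into the final posterior that makes even precise,
habit-free agents misread every intention flip.

Policy distributions combine three ingredients:

```
pi0 = softmax(gamma * (ln E - G))          E = e / sum(e)
pi  = softmax(gamma * (ln E - G) - F)
```

Policy precision `gamma = 1/beta` thus scales the *prior* ingredients —
habits and prospective value — against accumulated evidence. Scaling the
habit term by `gamma` (rather than leaving it bare) is a deliberate design
choice: it is what lets high policy precision reinforce the influence of
habits on inference, produces the habit-resistance-by-precision interaction,
and gives the precision-lowering treatment its ability to restore belief
updating without touching the habit counts themselves.
`beta` is updated after each timestep's evaluation by the innovation
`beta <- beta + (pi - pi0) . G` (floored at 1e-3) and carried across trials,
so confidence grows while events keep conforming to the agent's prospectus
and shrinks under surprise.

Actions: the trust/distrust stance is sampled from the alpha-sharpened
posterior mass on trusting policies; the card from the alpha-sharpened
model-averaged belief about the correct card. Choice precision `alpha`
touches nothing but this sampling. After the card is enacted, policies
prescribing the other card are pruned. Habits then accumulate the final
policy posterior, one count per trial in total; beliefs about the advisor
reported for a trial are the Bayesian model average (the posterior mass on
trusting policies) at the final timestep.

## What the generator emulates, and what it does not

The task environment *is* the study's data generator: trustworthiness
schedules (consistently trustworthy, or 125 untrustworthy then 125
trustworthy trials with an "initial consistency" rotation of 1–125), uniform
random correct cards, the 10% per-trial intention flip, truthful feedback,
and arousal coupled to the sampled stance through the 2/3–1/3 affect
transitions. It does not emulate: a reactive advisor (the advisor never
responds to the agent), across-trial volatility or hierarchical inference,
mood change over time, or feedback noise. Passing tests therefore speak to
the internal dynamics of belief/habit/precision coupling, not to fits of
human data.

## The simulation study

`run_sweep()` reproduces the five simulation sets (972 agents each):
parameters drawn independently and uniformly from `a` in [0.60, 0.99], `e0`
in [2, 600], initial consistency 1–125, mood in [-4.5, 4.5], `alpha` in
[0.5, 2.75], `1/beta` in [0.25, 1.75]. A run is scored by `assess_agent()`:
false inferences (posterior on the wrong side of 0.5 against the realized
intention), the delusion score (falsity + mean confidence of false
inferences + incorrigibility), classification at the 66% (60%, 70%)
thresholds with the falsity threshold halved for changing sequences,
habit strength `|ln(e_trust/e_distrust)|`, and habit-based delusion-like
priors. Sweep summaries give delusion frequencies, Spearman correlations
(absolute mood for changing sequences), and a standardized regression with
all pairwise interactions, reporting significance at p < 0.05.

The treatment hook halves the excess of `1/beta` over the population minimum
(0.25) once an agent has made 10 false inferences; the reduced value then
persists — later precision growth is capped at the treated level — which is
what makes the intervention durable rather than transient under the
carried-precision dynamics.

```{r example, eval = FALSE}
run <- run_agent(
  agent_config(a = 0.75, e0 = 2, mood = -1, affect = TRUE, seed = 1),
  make_sequence("changing_trustworthiness", seed = 1)
)
assess_agent(run)
```

## Numerical choices

* All logarithms use an additive 1e-16 floor (deterministic arrays contain
  exact zeros); evidence vectors carry the same floor so that pruned
  policies retain a vanishing, never zero, likelihood.
* `beta` is floored at 1e-3; probability sums are clamped to [0, 1] before
  sharpened sampling to absorb float overshoot.
* Tie rule: a posterior of exactly 0.5 is not a false inference; delusion
  criteria use strict inequalities; a flagged final trial is excluded from
  the incorrigibility denominator (its successor is undefined).
* Seeding: one generator per agent, seeded from the configuration;
  environment and agent draws interleave in a fixed order, so a
  (configuration, sequence) pair reproduces a run bit-for-bit, and sweeps
  derive all per-agent seeds from one master seed.

## Open design points and their resolutions

The source scheme for this family of models leaves several details open;
the package fixes them as follows (alternatives remain selectable through
`scheme_options()` for comparison):

* *Habit term in policy selection*: included inside both softmaxes, scaled
  by `gamma` (see above). With uniform counts it vanishes, recovering the
  bare `softmax(-gamma G)` prior.
* *Habit increments*: the full final policy posterior, so habits can
  self-reinforce; the likelihood-only "responsibility" variant caps the
  habit odds at the evidence base rate and cannot produce the observed
  false-inference regimes.
* *Trust pinning*: the printed deterministic mapping; a "soft" variant
  composing it with the 10% instability is available.
* *Arousal timing*: emitted at every timestep (the affect loop needs the
  advice-stage arousal observation to drive precision dynamics); affect
  transitions apply at each within-trial transition.
* *Precision carry-over*: the trial-final `beta` becomes the next trial's
  prior. This is what lets precision grow along the habit attractor; its
  cost is that realized precision decouples from the configured prior over
  long runs.

## Problem sizes and limitations

The packaged tests exercise the study at reduced scale (200-agent sweeps,
20-seed benchmark agents); `scripts/acceptance.R` runs the full 972-agent
sweeps. Known quantitative sensitivities of the scheme: the habit benefit
to choice accuracy saturates quickly (the alpha-sharpened choice rule turns
a 0.8 habit fraction into near-0.9 following rates); the habit-resistance
gradient is compressed over the upper half of its range, since only 250
counts can accumulate against initial counts of up to 600; the correlation
between the *configured* precision prior and downstream delusion scores is
diluted by the carried-precision dynamics, which let realized precision
drift from its prior; and arousal evidence (2 × ln 2 per trial) can outweigh
weak-likelihood feedback in non-habit agents, producing scattered wrong-side
posteriors that inflate the share of agents with at least one false
inference. These trade-offs are documented rather than patched, because
every variant we examined that removes one of them destroys a
better-established property of the model (see `scheme_options()` and the
design-points section above).
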