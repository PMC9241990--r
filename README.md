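# delusim

Active-inference simulations of delusion formation in an advisor/card task.

## The problem

Delusions are beliefs that are false, held with near certainty, and
resistant to contradictory evidence — puzzling properties for a brain that
approximates Bayesian inference. `delusim` implements a discrete-state
active-inference (POMDP) agent that can develop exactly such beliefs from
moderate, individually unremarkable parameter settings, and the simulation
study around it: per-trial inference dynamics, delusion scoring, 972-agent
parameter sweeps, and a simulated antipsychotic intervention that lowers
policy precision. It is aimed at computational-psychiatry researchers who
want a self-contained, reproducible implementation of habit/precision
attractor dynamics in belief updating.

## The model in brief

On each of 250 trials an advisor (trustworthy or untrustworthy; the
realized intention flips from its schedule with probability 0.1) names one
of two cards; the agent chooses a card and receives feedback it believes
correct with probability *a* (its likelihood precision). The agent holds a
generative model with five hidden-state factors (advisor intention, correct
card, its own decision, affect, trial stage) and evaluates four whole-trial
policies π ∈ {trust, distrust} × {blue, green}. Per policy it infers states
exactly (the within-trial model is a 72-state hidden Markov chain), giving
free energy F(π); expected free energy G(π) scores not-yet-seen outcomes by
risk plus ambiguity under log-preferences **c** (feedback `[3, −3, 0]`;
arousal `[c, −c]`, the mood parameter). Policies are selected as

    π0 = σ( γ (ln E − G) ),    π = σ( γ (ln E − G) − F ),

where E are normalized Dirichlet habit counts (initialized at the
"habit resistance" e0, incremented by the final policy posterior each
trial) and the policy precision γ = 1/β is updated by the innovation
β ← β + (π − π0)·G and carried across trials. Trusting is a mental action
that pins the advisor trustworthy in the agent's model, so the reported
belief about the advisor is the posterior mass on trusting policies
(Bayesian model averaging). A run is scored for false inferences (posterior
on the wrong side of 0.5 against the realized intention) and a delusion
score = falsity + certainty + incorrigibility, with classification
thresholds of 66% (60%/70% variants).

See `vignettes/delusion-attractors.Rmd` for the full account, including the
design decisions taken where the scheme is underdetermined.

## Worked example

A habit-forming agent with modestly reduced likelihood precision and mildly
negative mood, on the sequence whose advisor turns trustworthy after 125
trials:

```r
library(delusim)
run <- run_agent(
  agent_config(a = 0.75, e0 = 2, mood = -1, affect = TRUE,
               inv_beta = 1, alpha = 1.5, seed = 1),
  make_sequence("changing_trustworthiness", seed = 1)
)
run
#> <agent_run> 250 trials on changing_trustworthiness
#>   correct choices: 49.2%  false inferences: 49.2%
#>   final habit counts: 8.2, 9.8, 115.8, 124.2   final 1/beta: 1.456
assess_agent(run)
#> <delusion_assessment> score 2.23 (falsity 0.49, certainty 0.92, incorrigibility 0.81)
#>   delusional (66% thresholds): TRUE   habit strength: 2.59
```

The agent entrenches a distrusting habit during the untrustworthy phase
(final counts concentrate on the two distrust policies), its policy
precision grows above its prior, and after the advisor turns trustworthy it
keeps inferring untrustworthiness on almost half the trials, with mean
confidence 0.92 and 81% of false inferences followed by another — false,
certain and incorrigible, hence classified delusional. The same agent
without affect, or with a = 0.9, is not.

Sweeps reproduce the study level:

```r
s <- run_sweep(simulation_set(4, n_agents = 200, master_seed = 1))
s$summary$delusion_frequency   # proportion classified delusional (66/60/70%)
s$summary$spearman             # parameter correlations with delusion score
```

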