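Package: delusim
Title: Active-Inference Simulations of Delusion Formation in an Advisor Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a discrete-state active-inference (partially observable
    Markov decision process) agent performing a 250-trial advisor/card task,
    together with the task's generative process, delusion scoring, and
    large-scale parameter sweeps. The agent infers hidden states (advisor
    trustworthiness, correct card, its own affect) by exact belief propagation
    under policy-conditioned generative models, selects policies by expected
    free energy with a learned Dirichlet habit prior and a dynamically updated
    policy precision (a dopamine analogue), and can be 'treated' by lowering
    that precision. Tools are provided to score false inferences, classify
    delusions by falsity, certainty and incorrigibility criteria, run
    multi-agent parameter sweeps with Spearman and regression summaries, and
    summarise belief/habit/precision trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
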