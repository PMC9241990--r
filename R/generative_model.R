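## Construction of the agent's generative model (lower-case arrays) and the
## environment's true generative process (upper-case arrays).

## Likelihood matrices (outcomes x 72 joint states) for all four modalities.
## `reliability` is the feedback reliability: the agent's `a` in its model,
## 0.9 in the true process.
make_likelihoods <- function(reliability, arousal_final = FALSE) {
  g <- joint_grid()
  n <- nrow(g)
  L <- list(
    advice   = matrix(0, 3, n),
    feedback = matrix(0, 3, n),
    arousal  = matrix(0, 3, n),
    choice   = matrix(0, 3, n)
  )
  for (j in seq_len(n)) {
    int <- g$intention[j]; card <- g$card[j]; dec <- g$decision[j]
    aff <- g$affect[j]; stg <- g$stage[j]

    ## advice: at the advice stage a trustworthy advisor names the correct
    ## card, an untrustworthy one the other card; null otherwise
    if (stg == 2L) {
      named <- if (int == 1L) card else 3L - card
      L$advice[1L + named, j] <- 1
    } else {
      L$advice[1L, j] <- 1
    }

    ## feedback: at the feedback stage, truthful with prob `reliability`
    if (stg == 3L && dec != 1L) {
      truthful <- (dec - 1L) == card
      L$feedback[1L, j] <- if (truthful) reliability else 1 - reliability
      L$feedback[2L, j] <- if (truthful) 1 - reliability else reliability
    } else {
      L$feedback[3L, j] <- 1
    }

    ## arousal: deterministic readout of affect (calm -> low), optionally
    ## interocepted only at the feedback stage
    if (arousal_final && stg != 3L) {
      L$arousal[3L, j] <- 1
    } else {
      L$arousal[aff, j] <- 1
    }

    ## observed choice: deterministic copy of the decision factor
    L$choice[dec, j] <- 1
  }
  L
}

## Per-factor transition matrices, as a list over the controllable settings.
## All are shared between the agent's model and the true process except the
## advisor-intention transition, which in the agent's model depends on the
## trust/distrust (mental) action.
make_transitions <- function() {
  list(
    intention = list(
      ## agent's model: trusting makes the advisor trustworthy, and conversely
      trust    = matrix(c(1, 0, 1, 0), 2, 2),
      distrust = matrix(c(0, 1, 0, 1), 2, 2),
      ## true process: the scheduled intention flips with prob 0.1 at trial
      ## start (realized once per trial, not per timestep)
      true     = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
    ),
    card = list(identity = diag(2)),
    decision = list(
      null  = matrix(rep(c(1, 0, 0), 3), 3, 3),
      blue  = matrix(rep(c(0, 1, 0), 3), 3, 3),
      green = matrix(rep(c(0, 0, 1), 3), 3, 3)
    ),
    affect = list(
      ## calm twice as likely under trust, angry twice as likely under distrust
      trust    = matrix(c(2 / 3, 1 / 3, 2 / 3, 1 / 3), 2, 2),
      distrust = matrix(c(1 / 3, 2 / 3, 1 / 3, 2 / 3), 2, 2)
    ),
    stage = list(advance = matrix(c(0, 1, 0,  0, 0, 1,  0, 0, 1), 3, 3))
  )
}

## Joint 72x72 transition matrix for one transition of one policy.
joint_transition <- function(b, trust, card_control, affect_moves = TRUE) {
  aff <- if (affect_moves) b$affect[[trust]] else diag(2)
  kronecker(b$stage$advance,
    kronecker(aff,
      kronecker(b$decision[[card_control]],
        kronecker(b$card$identity, b$intention[[trust]]))))
}

#' Build an agent's generative model
#'
#' Assembles the agent's likelihood arrays, policy-dependent transitions,
#' outcome preferences, initial-state priors, Dirichlet habit counts and
#' policy set from an [agent_config()].
#'
#' The model has five hidden-state factors (advisor intention, correct card,
#' card decision, affect, trial stage) and four outcome modalities (advice,
#' feedback, arousal, observed choice). Feedback is believed `a`-reliable;
#' the preference vector over feedback is `[3, -3, 0]` (correct, incorrect,
#' null), i.e. 'correct' is expected over 'incorrect' by a factor exp(6).
#' The arousal preference is `[mood, -mood]` (low, high) when affect is
#' enabled, zero otherwise. The four policies are
#' {trust, distrust} x {choose blue, choose green}; trusting maps the advisor
#' deterministically to 'trustworthy' in the agent's model (a mental action),
#' and, when affect is enabled, makes a calm state twice as likely as angry.
#'
#' @param config An [agent_config()].
#' @param intent_pinning `"hard"` (default): the trust action maps the
#'   advisor deterministically to the matching intention; `"soft"`: that map
#'   composed with the 10% within-trial intention instability.
#' @param arousal_obs,affect_transitions See [scheme_options()].
#' @return An object of class `delusim_model`.
#' @seealso [build_environment()], [run_agent()]
#' @export
#' @examples
#' m <- build_agent_model(agent_config(a = 0.75, e0 = 2, affect = TRUE, mood = -1))
#' m$c$arousal  # c(-1, 1, 0)
build_agent_model <- function(config, intent_pinning = c("hard", "soft"),
                              arousal_obs = c("all", "final"),
                              affect_transitions = c("each", "once")) {
  if (!inherits(config, "agent_config")) config <- do.call(agent_config, config)
  intent_pinning <- match.arg(intent_pinning)
  arousal_obs <- match.arg(arousal_obs)
  affect_transitions <- match.arg(affect_transitions)
  b <- make_transitions()
  if (intent_pinning == "soft") {
    b$intention$trust <- b$intention$true %*% b$intention$trust
    b$intention$distrust <- b$intention$true %*% b$intention$distrust
  }
  lik <- make_likelihoods(config$a, arousal_final = arousal_obs == "final")
  pol <- policy_set()

  cvec <- list(
    advice   = c(0, 0, 0),
    feedback = c(3, -3, 0),
    arousal  = if (config$affect) c(config$mood, -config$mood, 0) else c(0, 0, 0),
    choice   = c(0, 0, 0)
  )
  d <- list(
    intention = c(0.5, 0.5),
    card      = c(0.5, 0.5),
    decision  = c(1, 0, 0),
    affect    = c(0.5, 0.5),
    stage     = c(1, 0, 0)
  )
  d_joint <- Reduce(kronecker, rev(d))

  ## per-policy joint transitions for the two within-trial transitions; the
  ## card action is enacted on the final transition only
  Tpol <- lapply(seq_len(nrow(pol)), function(p) {
    list(
      joint_transition(b, pol$trust[p], "null"),
      joint_transition(b, pol$trust[p], pol$card[p],
                       affect_moves = affect_transitions == "each")
    )
  })

  ## precomputed expected-free-energy operators: for each policy and
  ## prediction horizon, outcome predictors O_m = a_m %*% T(cum) and the
  ## pooled ambiguity row vector h = sum_m H_m^T T(cum), so that one-step
  ## G terms reduce to a handful of 3 x 72 products
  H <- lapply(lik, col_entropy)
  efe_ops <- function(Tcum) {
    list(
      O = do.call(rbind, lik) %*% Tcum, # stacked over modalities
      h = as.vector(Reduce(`+`, H) %*% Tcum)
    )
  }
  Gpre <- lapply(seq_len(nrow(pol)), function(p) {
    T1 <- Tpol[[p]][[1]]; T2 <- Tpol[[p]][[2]]
    list(step1 = efe_ops(T1), step13 = efe_ops(T2 %*% T1), step2 = efe_ops(T2))
  })

  model <- structure(list(
    config = config,
    a = lik,
    b = b[c("intention", "card", "decision", "affect", "stage")],
    c = cvec,
    d = d,
    e = rep(config$e0, nrow(pol)),
    policies = pol,
    alpha = config$alpha,
    beta0 = 1 / config$inv_beta,
    affect_enabled = config$affect,
    d_joint = d_joint,
    Tpol = Tpol,
    H = H,
    Gpre = Gpre,
    c_flat = unlist(cvec, use.names = FALSE)
  ), class = "delusim_model")

  for (m in names(lik)) stopifnot_stochastic(lik[[m]], what = paste0("a$", m))
  for (p in seq_along(Tpol)) {
    stopifnot_stochastic(Tpol[[p]][[1]], what = "joint transition")
    stopifnot_stochastic(Tpol[[p]][[2]], what = "joint transition")
  }
  model
}

#' Build the task's true generative process
#'
#' The environment shares all arrays with the agent's model except for the
#' feedback likelihood (whose precision the agent's `a` parameterizes,
#' independently of the truth) and the advisor-intention dynamic, which is a
#' 10% per-trial flip of the scheduled intention rather than a
#' policy-dependent mapping.
#'
#' By default the realized feedback is truthful given the choice and the
#' correct card (`feedback_reliability = 1`): the only outcome noise the
#' agent faces is the intention flip (plus stochastic affect dynamics). This
#' is what makes a precise-likelihood, habit-resistant agent capable of
#' perfectly accurate trustworthiness inferences; independently noisy
#' feedback would mislead any Bayesian observer on the dishonest trials.
#' Set `feedback_reliability = 0.9` for a noisy-feedback variant.
#'
#' @param sequence A [make_sequence()] task sequence.
#' @param feedback_reliability Probability that emitted feedback is truthful.
#' @return An object of class `delusim_environment`.
#' @export
build_environment <- function(sequence, feedback_reliability = 1) {
  if (!inherits(sequence, "task_sequence")) {
    stop("`sequence` must be a task_sequence from make_sequence()")
  }
  b <- make_transitions()
  structure(list(
    sequence = sequence,
    A = make_likelihoods(feedback_reliability),  # arousal emission timing follows the agent's model
    B = b,
    flip_prob = b$intention$true[2, 1],
    feedback_reliability = feedback_reliability
  ), class = "delusim_environment")
}
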