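## The agent loop: one trial (three timesteps of observe - infer - evaluate
## policies - update precision - act) and a full 250-trial run carrying habit
## counts and precision across trials.

TRUST_POLICIES <- c(TRUE, TRUE, FALSE, FALSE) # order of policy_set()

#' Agent scheme options
#'
#' Collects the open structural choices of the belief-update scheme. The
#' defaults are the package's canonical scheme (see the methods vignette for
#' the rationale); the alternatives are retained for comparison.
#'
#' @param choice_rule How the card is sampled at the choice point:
#'   `"bma_card"` (default) samples from the alpha-sharpened model-averaged
#'   belief about the correct card; `"policy_marginal"` samples from the
#'   alpha-scaled marginal of the policy posterior over card actions.
#' @param habit_update `"posterior"` (default) accumulates the full final
#'   policy posterior (including the habit prior itself, so habits can
#'   self-reinforce); `"responsibility"` credits habit counts by the
#'   likelihood-only policy responsibility `softmax(-F)`.
#' @param intent_pinning `"hard"` uses the printed deterministic
#'   trust/distrust transition of the advisor-intention factor; `"soft"`
#'   composes it with the 10% within-trial instability.
#' @param scale_habit Scale the habit log-prior by policy precision `gamma`
#'   in the policy distributions (default `TRUE`); see
#'   [policy_distributions()].
#' @param arousal_obs Whether arousal is interocepted at `"all"` timesteps
#'   (default) or only at the `"final"` (feedback) stage.
#' @param beta_carry Carry the posterior `beta` across trials as the next
#'   trial's prior (default) or re-anchor it at the configured prior each
#'   trial.
#' @param affect_transitions Apply the policy-dependent affect transition at
#'   `"each"` within-trial transition (default) or `"once"`, at trial start,
#'   after which affect persists within the trial.
#' @return List of class `scheme_options`.
#' @export
scheme_options <- function(choice_rule = c("bma_card", "policy_marginal"),
                           habit_update = c("posterior", "responsibility"),
                           intent_pinning = c("hard", "soft"),
                           scale_habit = TRUE,
                           arousal_obs = c("all", "final"),
                           affect_transitions = c("each", "once"),
                           beta_carry = TRUE) {
  structure(list(
    choice_rule = match.arg(choice_rule),
    habit_update = match.arg(habit_update),
    intent_pinning = match.arg(intent_pinning),
    scale_habit = isTRUE(scale_habit),
    arousal_obs = match.arg(arousal_obs),
    affect_transitions = match.arg(affect_transitions),
    beta_carry = isTRUE(beta_carry)
  ), class = "scheme_options")
}

## Internal fast trial core: returns a named numeric vector plus the updated
## state. run_trial() wraps it in a one-row data.frame.
REC_FIELDS <- c("trial", "scheduled_intention", "true_intention",
                "correct_card", "advice", "choice", "correct", "feedback",
                "arousal", "trust_action", "prior_trust", "posterior_trust",
                "trust_action_posterior", "false_inference", "gamma_T",
                "beta", "e_trust", "e_distrust", "e_blue", "e_green")

trial_core <- function(model, env, trial_index, state, opts) {
  seqn <- env$sequence
  realized <- realize_trial(seqn, trial_index, env$flip_prob)
  true_int <- realized$true_intention
  advice <- realized$advice
  card_true <- seqn$correct_card[trial_index]
  affect_on <- model$affect_enabled
  scale_habit <- opts$scale_habit
  bma_choice <- opts$choice_rule == "bma_card"

  ## true affect state: each trial begins anew with uniform affect
  affect_now <- if (affect_on) sample_index(c(0.5, 0.5)) else NA_integer_

  active <- 1:4
  e <- state$e
  beta <- state$beta
  gamma <- 1 / beta
  lnE <- log(e / sum(e))
  alpha <- model$alpha

  f <- vector("list", 4L) # filtered joint posterior per policy
  Fv <- numeric(4L)       # accumulated -log evidence per policy

  step_evidence <- function(tau, obs) {
    ev <- evidence_vector(model, obs)
    for (p in active) {
      pred <- if (tau == 1) model$d_joint
              else as.vector(model$Tpol[[p]][[tau - 1L]] %*% f[[p]])
      x <- pred * ev
      z <- sum(x)
      Fv[p] <<- Fv[p] - log(z)
      f[[p]] <<- x / z
    }
  }
  pol_dist <- function(G) {
    w <- if (scale_habit) gamma else 1
    base <- w * lnE[active] - gamma * G[active]
    list(pi0 = softmax(base), pi = softmax(base - Fv[active]))
  }
  sample_binary <- function(p1) { # alpha-sharpened two-outcome draw
    p1 <- min(max(p1, 0), 1)      # guard float overshoot of probability sums
    ps <- softmax(alpha * log_safe(c(p1, 1 - p1)))
    sample_index(ps)
  }
  trust_mass <- function(pi) sum(pi[active <= 2L])
  arousal_now <- function(tau) {
    if (!affect_on) return(NA_integer_)
    if (opts$arousal_obs == "final" && tau < 3L) return(3L) # null level
    emit_arousal(affect_now)
  }

  ## --- timestep 1: trial start -------------------------------------------
  step_evidence(1L, c(1L, 3L, arousal_now(1L), 1L))
  G <- numeric(4L)
  for (p in active) G[p] <- expected_free_energy(model, f[[p]], p, 1L)
  pd <- pol_dist(G)
  prior_trust <- trust_mass(pd$pi0)
  up <- update_precision(beta, pd$pi, pd$pi0, G[active])
  beta <- up$beta_posterior; gamma <- up$gamma
  u_trust <- sample_binary(trust_mass(pd$pi)) # 1 = trust, 2 = distrust
  if (affect_on) {
    affect_now <- transition_affect(model$b$affect,
                                    c("trust", "distrust")[u_trust],
                                    affect_now)
  }

  ## --- timestep 2: advice ------------------------------------------------
  step_evidence(2L, c(1L + advice, 3L, arousal_now(2L), 1L))
  for (p in active) G[p] <- expected_free_energy(model, f[[p]], p, 2L)
  pd <- pol_dist(G)
  up <- update_precision(beta, pd$pi, pd$pi0, G[active])
  beta <- up$beta_posterior; gamma <- up$gamma
  choice <- if (bma_choice) {
    ## sample the card the agent believes correct: alpha-sharpened Bayesian
    ## model average of the correct-card belief at the choice point
    bl <- BLUE_IND()
    q_blue <- sum(vapply(seq_along(active), function(k) {
      pd$pi[k] * sum(f[[active[k]]][bl])
    }, numeric(1)))
    sample_binary(q_blue)
  } else {
    ## alpha-scaled marginal of the policy posterior over card actions
    sample_binary(sum(pd$pi[active %in% c(1L, 3L)]))
  }
  u_trust <- sample_binary(trust_mass(pd$pi))
  if (affect_on && opts$affect_transitions == "each") {
    affect_now <- transition_affect(model$b$affect,
                                    c("trust", "distrust")[u_trust],
                                    affect_now)
  }
  feedback <- emit_feedback(choice, card_true, env$feedback_reliability)

  ## card action enacted: prune policies prescribing the other card
  active <- if (choice == 1L) c(1L, 3L) else c(2L, 4L)

  ## --- timestep 3: choice and feedback -----------------------------------
  obs3 <- c(1L, feedback, arousal_now(3L), 1L + choice)
  step_evidence(3L, obs3)
  ## no unobserved future remains: G = 0, so pi = softmax(gamma lnE - F) and
  ## the precision innovation vanishes
  pd <- pol_dist(numeric(4L))
  pi_final <- numeric(4L); pi_final[active] <- pd$pi
  ## habit increment: full posterior, or likelihood-only responsibility
  ## softmax(-F) crediting policies by the trial evidence alone
  pi_habit <- if (opts$habit_update == "responsibility") {
    w <- numeric(4L); w[active] <- softmax(-Fv[active]); w
  } else pi_final

  ## Bayesian model average of the trustworthiness belief at the final
  ## timestep (trusting policies pin the advisor trustworthy, so this equals
  ## the posterior mass on trusting policies)
  tind <- TRUST_IND()
  posterior_trust <- sum(vapply(active, function(p) {
    pi_final[p] * sum(f[[p]][tind])
  }, numeric(1)))

  e <- e + pi_habit
  state$e <- e
  state$beta <- beta
  p_realized <- if (true_int == 1L) posterior_trust else 1 - posterior_trust

  vec <- c(trial_index, seqn$scheduled_intention[trial_index], true_int,
           card_true, advice, choice, as.numeric(choice == card_true),
           feedback, if (affect_on) obs3[3] else NA_real_, u_trust,
           prior_trust, posterior_trust, pi_final[1] + pi_final[2],
           as.numeric(p_realized < 0.5), gamma, beta,
           e[1] + e[2], e[3] + e[4], e[1] + e[3], e[2] + e[4])
  list(vec = vec, state = state)
}

#' Run one trial
#'
#' Executes the three-timestep loop for one trial: realize the advisor's
#' intention and advice, then at each timestep update the policy-conditioned
#' state posteriors (exact filtering over the joint state space), evaluate
#' the expected free energy of each policy over the remaining timesteps, form
#' the policy prior/posterior, update policy precision, and sample the
#' trust/distrust (mental) action and, at the choice point, the card. After
#' the card is enacted, policies prescribing the other card are pruned (their
#' evidence collapses); trust/distrust remains revisable up to the final
#' timestep. Habits accumulate the final policy posterior.
#'
#' Draws use the current RNG state; [run_agent()] manages seeding.
#'
#' @param model A [build_agent_model()] model.
#' @param env A [build_environment()] process.
#' @param trial_index Trial number.
#' @param state Agent state list carried across trials: `e` (habit counts),
#'   `beta` (current precision prior). See [run_agent()].
#' @param opts Scheme options from [scheme_options()].
#' @return List with `record` (one-row data.frame with, per trial, the
#'   realized states, outcomes, actions, belief summaries and habit/precision
#'   snapshots) and the updated `state`.
#' @export
run_trial <- function(model, env, trial_index, state,
                      opts = scheme_options()) {
  out <- trial_core(model, env, trial_index, state, opts)
  rec <- as.data.frame(as.list(stats::setNames(out$vec, REC_FIELDS)))
  rec$correct <- as.logical(rec$correct)
  rec$false_inference <- as.logical(rec$false_inference)
  list(record = rec, state = out$state)
}

## cached indicators of joint states (trustworthy advisor; blue correct card)
TRUST_IND <- local({
  ind <- NULL
  function() {
    if (is.null(ind)) ind <<- joint_grid()$intention == 1L
    ind
  }
})
BLUE_IND <- local({
  ind <- NULL
  function() {
    if (is.null(ind)) ind <<- joint_grid()$card == 1L
    ind
  }
})

#' Run an agent through a task sequence
#'
#' Runs `n_trials` trials, carrying habit counts `e` and the policy-precision
#' prior `beta` from trial to trial, with an optional simulated antipsychotic
#' treatment that permanently lowers `1/beta` once the agent has made 10
#' false inferences (see [apply_treatment()]).
#'
#' All randomness (environment and agent) is driven by one generator seeded
#' from `config$seed`, so a `(config, sequence)` pair fully reproduces a run.
#'
#' @param config An [agent_config()] (or list of its arguments).
#' @param sequence A [make_sequence()] task sequence.
#' @param n_trials Number of trials (default: the sequence length).
#' @param treatment `NULL`, or a list such as `treatment_spec()` with fields
#'   `threshold` (false inferences before onset) and `min_inv_beta`.
#' @return An object of class `agent_run`: list with `records` (one-row-per-
#'   trial data.frame), `final_e`, `final_beta`, `treated_at` (trial index or
#'   NA), `config`, and sequence metadata.
#' @export
#' @examples
#' run <- run_agent(agent_config(a = 0.9, e0 = 2, seed = 1),
#'                  make_sequence("consistently_trustworthy", seed = 1),
#'                  n_trials = 25)
#' mean(run$records$correct)
run_agent <- function(config, sequence, n_trials = sequence$n_trials,
                      treatment = NULL, opts = scheme_options()) {
  if (!inherits(config, "agent_config")) config <- do.call(agent_config, config)
  model <- build_agent_model(config, intent_pinning = opts$intent_pinning,
                             arousal_obs = opts$arousal_obs,
                             affect_transitions = opts$affect_transitions)
  env <- build_environment(sequence)
  state <- list(e = model$e, beta = model$beta0, beta_prior = model$beta0)
  treated_at <- NA_integer_
  n_false <- 0L

  set.seed(config$seed)
  rows <- matrix(NA_real_, n_trials, length(REC_FIELDS),
                 dimnames = list(NULL, REC_FIELDS))
  for (t in seq_len(n_trials)) {
    if (!opts$beta_carry) state$beta <- state$beta_prior
    ## sustained medication: the reduced 1/beta persists for the rest of the
    ## run, capping any later precision growth at the treated level
    if (!is.na(treated_at)) state$beta <- max(state$beta, state$beta_prior)
    out <- trial_core(model, env, t, state, opts)
    state <- out$state
    rows[t, ] <- out$vec
    n_false <- n_false + out$vec[[14]] # false_inference flag
    if (!is.null(treatment) && is.na(treated_at) &&
        n_false >= treatment$threshold) {
      tr <- function(x) 1 / apply_treatment(1 / x, n_false,
                                            threshold = treatment$threshold,
                                            min_inv_beta = treatment$min_inv_beta)
      state$beta <- tr(state$beta)
      state$beta_prior <- tr(state$beta_prior)
      treated_at <- t
    }
  }
  records <- as.data.frame(rows)
  records$correct <- records$correct > 0
  records$false_inference <- records$false_inference > 0
  structure(list(
    records = records,
    final_e = state$e,
    final_beta = state$beta,
    treated_at = treated_at,
    config = config,
    sequence_kind = sequence$kind,
    initial_consistency = sequence$initial_consistency
  ), class = "agent_run")
}

#' @export
print.agent_run <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<agent_run> %d trials on %s\n  correct choices: %.1f%%  false inferences: %.1f%%%s\n",
    nrow(r), x$sequence_kind, 100 * mean(r$correct),
    100 * mean(r$false_inference),
    if (!is.na(x$treated_at)) sprintf("  (treated at trial %d)", x$treated_at)
    else ""))
  cat(sprintf("  final habit counts: %s   final 1/beta: %.3f\n",
              paste(formatC(x$final_e, format = "f", digits = 1),
                    collapse = ", "), 1 / x$final_beta))
  invisible(x)
}

#' Write an agent run to CSV (plus JSON sidecar)
#'
#' One CSV row per trial mirroring the trial record; the sidecar JSON stores
#' the configuration and the final habit counts and precision.
#'
#' @param run An [run_agent()] result.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_agent_run <- function(run, path) {
  utils::write.csv(run$records, path, row.names = FALSE)
  meta <- list(
    config = unclass(run$config),
    final_e = run$final_e,
    final_beta = run$final_beta,
    treated_at = run$treated_at,
    sequence_kind = run$sequence_kind,
    initial_consistency = run$initial_consistency
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
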