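## Within-trial variational inference: policy-conditioned state posteriors,
## variational free energy F, expected free energy G, policy prior/posterior,
## precision updates, Bayesian model averaging, action selection and habit
## accumulation.

## Indicator matrices mapping the 72-state joint onto per-factor marginals.
factor_marginalizers <- function() {
  g <- joint_grid()
  out <- list()
  for (fct in names(FACTOR_DIMS)) {
    M <- matrix(0, FACTOR_DIMS[[fct]], nrow(g))
    M[cbind(g[[fct]], seq_len(nrow(g)))] <- 1
    out[[fct]] <- M
  }
  out
}

## Evidence vector over the 72 joint states for one timestep's observations.
## `obs` is an integer vector of outcome indices named/ordered as
## MODALITY_LEVELS; NA marks modalities not observed (e.g. arousal when
## affect is disabled). A vanishing floor keeps impossible states at a tiny,
## not zero, likelihood.
evidence_vector <- function(model, obs) {
  ev <- rep(1, N_JOINT)
  for (m in seq_along(model$a)) {
    if (!is.na(obs[m])) ev <- ev * model$a[[m]][obs[m], ]
  }
  ev + .LOG_FLOOR
}

#' Infer hidden states under one policy
#'
#' Computes the policy-conditioned posterior over all five hidden-state
#' factors at all three timesteps, given the outcomes observed so far, along
#' with the variational free energy F of the policy. Because the within-trial
#' model is a three-step hidden Markov chain over a 72-element joint state
#' space, belief propagation (a single forward-backward sweep of marginal
#' messages) reaches the free-energy minimum exactly; the sweep loop exits as
#' soon as F stops changing (tolerance 1/128 nats, cap 16 sweeps) and warns,
#' rather than fails, if the cap is ever hit.
#'
#' Timesteps beyond the observed ones are predicted forward under the
#' policy's transitions. F equals the negative log evidence of the observed
#' outcomes under the policy.
#'
#' @param model A [build_agent_model()] model.
#' @param observations Integer matrix with one column per observed timestep
#'   (1 to 3) and four rows (advice, feedback, arousal, choice outcome
#'   indices; NA = modality not observed). A list of per-timestep vectors is
#'   also accepted.
#' @param policy Policy index in `1:4` (see `model$policies`).
#' @param max_sweeps,tol Sweep cap and F convergence tolerance in nats.
#' @return List with `posteriors` (list over factors of `levels x 3`
#'   matrices), `joint` (72 x 3 matrix of joint posteriors) and `F` (nats).
#' @export
infer_states <- function(model, observations, policy, max_sweeps = 16,
                         tol = 1 / 128) {
  if (is.list(observations)) {
    observations <- vapply(observations, as.integer, integer(4))
  }
  observations <- as.matrix(observations)
  n_obs <- ncol(observations)
  stopifnot(n_obs >= 1, n_obs <= 3, nrow(observations) == 4)
  Tr <- model$Tpol[[policy]]

  ev <- lapply(seq_len(n_obs), function(tau) {
    evidence_vector(model, observations[, tau])
  })

  F_prev <- Inf
  for (sweep in seq_len(max_sweeps)) {
    ## forward (filtering) messages over observed timesteps
    fwd <- matrix(0, N_JOINT, 3)
    logz <- numeric(n_obs)
    f <- model$d_joint * ev[[1]]
    logz[1] <- log(sum(f))
    fwd[, 1] <- f / sum(f)
    for (tau in seq_len(2)) {
      pred <- Tr[[tau]] %*% fwd[, tau]
      if (tau + 1 <= n_obs) {
        f <- as.vector(pred) * ev[[tau + 1]]
        logz[tau + 1] <- log(sum(f))
        fwd[, tau + 1] <- f / sum(f)
      } else {
        fwd[, tau + 1] <- pred # prediction, no evidence yet
      }
    }
    F_cur <- -sum(logz)
    if (abs(F_cur - F_prev) < tol) break
    F_prev <- F_cur
    if (sweep == max_sweeps) {
      warning("state inference hit the sweep cap; returning current estimate",
              call. = FALSE)
    }
  }

  ## backward (smoothing) pass over the observed segment
  post <- fwd
  if (n_obs >= 2) {
    bwd <- rep(1, N_JOINT)
    for (tau in seq(n_obs, 2)) {
      post[, tau] <- normalize(fwd[, tau] * bwd)
      bwd <- crossprod(Tr[[tau - 1]], ev[[tau]] * bwd)
      bwd <- as.vector(bwd) / max(bwd)
    }
    post[, 1] <- normalize(fwd[, 1] * bwd)
    for (tau in seq_len(2)) { # re-predict unobserved timesteps from smoothed
      if (tau + 1 > n_obs) post[, tau + 1] <- Tr[[tau]] %*% post[, tau]
    }
  }

  M <- factor_marginalizers()
  posteriors <- lapply(M, function(Mf) Mf %*% post)
  list(posteriors = posteriors, joint = post, F = F_cur)
}

## Risk + ambiguity of one timestep's predicted outcomes under predicted
## joint states `s`: sum_m [ o.(ln o - c_m) + s.H_m ], with o = a_m s.
efe_timestep <- function(model, s) {
  g <- 0
  for (m in seq_along(model$a)) {
    o <- as.vector(model$a[[m]] %*% s)
    g <- g + sum(o * (log_safe(o) - model$c[[m]])) + sum(s * model$H[[m]])
  }
  g
}

#' Expected free energy of a policy
#'
#' Scores the outcomes a policy is expected to produce at the timesteps not
#' yet observed: `G = E[risk] + E[ambiguity]`, equivalently minus the
#' expected information gain minus the expected log-preference of predicted
#' outcomes. Lower G marks policies that resolve uncertainty and/or deliver
#' preferred outcomes ('correct' feedback; low arousal under positive mood).
#' At the final timestep there is no future left and G is zero for every
#' policy.
#'
#' @param model A [build_agent_model()] model.
#' @param state_posterior Joint 72-state posterior at timestep `tau` under
#'   the policy (e.g. column `tau` of `infer_states()$joint`).
#' @param policy Policy index.
#' @param tau Current (latest observed) timestep, 1 to 3.
#' @return G in nats (finite; logs are floored).
#' @export
expected_free_energy <- function(model, state_posterior, policy, tau) {
  if (tau >= 3) return(0)
  ops <- model$Gpre[[policy]]
  steps <- if (tau == 1) list(ops$step1, ops$step13) else list(ops$step2)
  G <- 0
  for (st in steps) {
    o <- st$O %*% state_posterior # stacked predicted outcomes, all modalities
    G <- G + sum(st$h * state_posterior) + sum(o * (log_safe(o) - model$c_flat))
  }
  G
}

#' Policy prior and posterior
#'
#' The prior combines the habit term and expected free energy,
#' `pi0 = softmax(gamma (ln E - G))` with `E = e / sum(e)`; the posterior
#' adds the evidence each policy has accrued,
#' `pi = softmax(gamma (ln E - G) - F)`.
#'
#' Policy precision `gamma` scales both prior ingredients — expected free
#' energy and the habit log-prior — against the accumulated evidence `F`.
#' This is what lets high policy precision reinforce the influence of habits
#' on inference (and lets the precision-lowering treatment restore belief
#' updating without touching habit strength itself). With uniform habit
#' counts the habit term vanishes and the distributions reduce to
#' `softmax(-gamma G)` and `softmax(-F - gamma G)`.
#'
#' @param G,F Numeric vectors over policies (nats).
#' @param e Positive Dirichlet habit counts over policies.
#' @param gamma Policy precision (> 0).
#' @param scale_habit Logical; scale the habit log-prior by `gamma` (default)
#'   or leave it unscaled.
#' @return List with components `pi0` and `pi`, both normalized.
#' @export
#' @examples
#' policy_distributions(G = c(0, 1), F = c(0, 0), e = c(1, 1), gamma = 1)$pi
policy_distributions <- function(G, F, e, gamma, scale_habit = TRUE) {
  stopifnot(gamma > 0, all(e > 0))
  lnE <- log(e / sum(e))
  w <- if (scale_habit) gamma else 1
  list(
    pi0 = softmax(w * lnE - gamma * G),
    pi  = softmax(w * lnE - F - gamma * G)
  )
}

#' Update policy precision
#'
#' Implements the precision dynamics `beta_post = beta + (pi - pi0) . G`,
#' `gamma = 1 / beta_post`. When the posterior shifts mass towards policies
#' with lower expected free energy than the prior anticipated (things are
#' unfolding as hoped), beta falls and confidence gamma rises; surprises push
#' gamma down. `beta_post` is floored at a small positive constant.
#'
#' @param beta_prior Current beta (> 0).
#' @param pi,pi0 Policy posterior and prior (same length as `G`).
#' @param G Expected free energies.
#' @param beta_min Floor for beta (default 1e-3).
#' @return List with `beta_posterior` and `gamma`.
#' @export
#' @examples
#' update_precision(1, pi = c(0.8, 0.2), pi0 = c(0.5, 0.5), G = c(1, 2))
update_precision <- function(beta_prior, pi, pi0, G, beta_min = 1e-3) {
  stopifnot(beta_prior > 0)
  b <- max(beta_prior + sum((pi - pi0) * G), beta_min)
  list(beta_posterior = b, gamma = 1 / b)
}

#' Bayesian model average of state posteriors
#'
#' Averages policy-conditioned posteriors under the policy distribution:
#' `Q(s) = sum_pi Q(s | pi) Q(pi)`. This is the route by which habits and
#' policy precision shape beliefs about the world. Accepts either plain
#' probability vectors/matrices or the per-factor posterior lists returned by
#' [infer_states()].
#'
#' @param state_posteriors List (one element per policy) of numeric vectors,
#'   matrices, or lists of factor posteriors.
#' @param pi Policy distribution, same length as `state_posteriors`.
#' @return Object of the same shape as one element of `state_posteriors`.
#' @export
bma_states <- function(state_posteriors, pi) {
  stopifnot(length(state_posteriors) == length(pi))
  pi <- pi / sum(pi)
  one <- state_posteriors[[1]]
  if (is.list(one)) {
    out <- lapply(seq_along(one), function(k) {
      Reduce(`+`, Map(function(sp, w) w * sp[[k]], state_posteriors, pi))
    })
    names(out) <- names(one)
    out
  } else {
    Reduce(`+`, Map(`*`, state_posteriors, pi))
  }
}

#' Sample an action from the policy posterior
#'
#' Marginalizes the policy posterior over policies sharing each action, then
#' samples from `softmax(alpha * ln p(u))`, i.e. `p(u)^alpha` renormalized.
#' Choice precision `alpha` affects only this sampling, never inference.
#'
#' @param pi Policy posterior.
#' @param actions Character (or factor) vector giving each policy's action on
#'   the controlled dimension (e.g. `c("trust","trust","distrust","distrust")`).
#' @param alpha Choice precision (> 0).
#' @return List with `action` (sampled label), `p_marginal` (marginal action
#'   probabilities before alpha scaling) and `p_sample` (after).
#' @export
select_action <- function(pi, actions, alpha) {
  stopifnot(alpha > 0, length(pi) == length(actions))
  p <- tapply(pi, actions, sum)
  p <- p[unique(actions)] # keep first-appearance order
  p <- as.vector(p) / sum(p)
  ps <- softmax(alpha * log_safe(p))
  k <- sample_index(ps)
  list(action = unique(actions)[k], p_marginal = stats::setNames(p, unique(actions)),
       p_sample = stats::setNames(ps, unique(actions)))
}

#' Accumulate habit counts
#'
#' Adds the final-timestep policy posterior to the Dirichlet habit counts:
#' a policy gains one full count when certainly chosen, otherwise mass
#' proportional to its posterior probability. Counts never decrease.
#'
#' @param e Current habit counts.
#' @param pi_posterior_final Final-timestep policy posterior (same length).
#' @return Updated counts.
#' @export
update_habits <- function(e, pi_posterior_final) {
  stopifnot(length(e) == length(pi_posterior_final),
            all(pi_posterior_final >= 0))
  e + pi_posterior_final
}
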