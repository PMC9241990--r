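# Brute-force enumeration oracle for within-trial state inference: computes
# the exact posterior over the 72-state joint at each timestep by summing the
# unnormalized probability of every (s1, s2, s3) state trajectory, with no
# message passing. Deliberately independent of the package's filtering code.
brute_force_posterior <- function(model, observations, policy) {
  observations <- as.matrix(observations)
  n_obs <- ncol(observations)
  ev <- lapply(1:3, function(tau) {
    if (tau <= n_obs) delusim:::evidence_vector(model, observations[, tau])
    else rep(1, N_JOINT())
  })
  T1 <- model$Tpol[[policy]][[1]]
  T2 <- model$Tpol[[policy]][[2]]
  d <- model$d_joint

  idx <- expand.grid(s1 = seq_len(N_JOINT()), s2 = seq_len(N_JOINT()))
  w12 <- d[idx$s1] * ev[[1]][idx$s1] * T1[cbind(idx$s2, idx$s1)] * ev[[2]][idx$s2]
  # for each (s1, s2) pair, sum over s3 trajectories
  sum3 <- as.vector(colSums(T2 * ev[[3]]))  # sum_s3 T2[s3, s2] ev3[s3]
  w_pair <- w12 * sum3[idx$s2]
  Z <- sum(w_pair)

  m1 <- rowsum(w_pair, idx$s1)[, 1] / Z
  m2 <- rowsum(w_pair, idx$s2)[, 1] / Z
  # marginal at timestep 3: weight each s2 by its pair mass, push through T2*ev3
  w2 <- rowsum(w12, idx$s2)[, 1]
  m3_un <- (T2 %*% (w2)) * ev[[3]]
  m3 <- as.vector(m3_un) / sum(m3_un)

  list(joint = cbind(m1, m2, m3), F = -log(Z))
}

N_JOINT <- function() nrow(delusim:::joint_grid())

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# random but stage-consistent observation matrices for 1..3 observed timesteps
random_observations <- function(n_obs, affect = TRUE) {
  arous <- function() if (affect) sample(1:2, 1) else NA_integer_
  obs <- cbind(c(1L, 3L, arous(), 1L))
  if (n_obs >= 2) obs <- cbind(obs, c(sample(2:3, 1), 3L, arous(), 1L))
  if (n_obs >= 3) {
    choice <- sample(2:3, 1)
    obs <- cbind(obs, c(1L, sample(1:2, 1), arous(), choice))
  }
  obs
}
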