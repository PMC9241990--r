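test_that("state inference matches brute-force enumeration over the joint", {
  set.seed(42)
  for (case in 1:12) {
    affect <- case %% 2 == 0
    cfg <- agent_config(a = sample(c(0.6, 0.75, 0.9), 1),
                        e0 = 2, mood = runif(1, -2, 2), affect = affect)
    m <- build_agent_model(cfg)
    n_obs <- sample(1:3, 1)
    obs <- random_observations(n_obs, affect)
    p <- sample(1:4, 1)
    got <- infer_states(m, obs, p)
    want <- brute_force_posterior(m, obs, p)
    for (tau in 1:3) {
      expect_lt(total_variation(got$joint[, tau], want$joint[, tau]), 1e-3)
    }
    expect_equal(got$F, want$F, tolerance = 1e-8)
  }
})

test_that("uninformative feedback leaves the card posterior at its prior", {
  ## a = 0.5 makes the feedback likelihood flat over correct/incorrect
  m <- build_agent_model(agent_config(a = 0.5))
  obs <- cbind(c(1L, 3L, NA, 1L), c(2L, 3L, NA, 1L), c(1L, 1L, NA, 2L))
  st <- infer_states(m, obs, policy = 1) # trust/blue
  ## advice pins the card under a trusting policy; feedback adds nothing:
  ## posterior over card at timestep 3 equals the advice-implied card exactly
  expect_equal(as.vector(st$posteriors$card[, 3]), c(1, 0), tolerance = 1e-9)
  ## and with flat feedback F is identical whether feedback was right or wrong
  obs2 <- obs; obs2[2, 3] <- 2L
  expect_equal(infer_states(m, obs2, 1)$F, st$F, tolerance = 1e-9)
})

test_that("correct feedback supports the advice-consistent trusting policy", {
  m <- build_agent_model(agent_config(a = 0.9, e0 = 600))
  ## advice blue, chose blue, feedback correct
  obs <- cbind(c(1L, 3L, NA, 1L), c(2L, 3L, NA, 1L), c(1L, 1L, NA, 2L))
  Ft <- infer_states(m, obs, 1)$F # trust/blue
  Fd <- infer_states(m, obs, 3)$F # distrust/blue
  ## evidence ratio is a/(1-a) = 9
  expect_equal(Fd - Ft, log(0.9 / 0.1), tolerance = 1e-6)
  ## posterior over the advisor under the trusting policy is pinned
  st <- infer_states(m, obs, 1)
  expect_equal(as.vector(st$posteriors$intention[, 3]), c(1, 0),
               tolerance = 1e-9)
})

test_that("expected free energy decomposes into risk plus ambiguity", {
  m <- build_agent_model(agent_config(a = 0.8, e0 = 2))
  ## hand-computed check on a point state: feedback stage, card blue,
  ## decision blue: o = (0.8, 0.2, 0), H = entropy(0.8, 0.2)
  g <- delusim:::joint_grid()
  j <- which(g$intention == 1 & g$card == 1 & g$decision == 2 &
               g$affect == 1 & g$stage == 3)
  s <- numeric(nrow(g)); s[j] <- 1
  o <- c(0.8, 0.2)
  risk <- sum(o * (log(o) - c(3, -3)))
  ambiguity <- -sum(o * log(o))
  expect_equal(delusim:::efe_timestep(m, s), risk + ambiguity,
               tolerance = 1e-6)
})

test_that("a policy predicting preferred feedback scores ~6 nats lower", {
  ## two policies with identical predicted states except that one predicts
  ## 'correct' (+3) and the other 'incorrect' (-3) with certainty
  m <- build_agent_model(agent_config(a = 0.99, e0 = 2))
  obs <- cbind(c(1L, 3L, NA, 1L), c(2L, 3L, NA, 1L)) # advice blue
  s_match <- infer_states(m, obs, 1)$joint[, 2]    # trust/blue: will match
  s_mismatch <- infer_states(m, obs, 2)$joint[, 2] # trust/green: will not
  G_match <- expected_free_energy(m, s_match, 1, 2)
  G_mismatch <- expected_free_energy(m, s_mismatch, 2, 2)
  expect_equal(G_mismatch - G_match, 6, tolerance = 0.15)
})

test_that("expected free energy vanishes once everything is observed", {
  m <- build_agent_model(agent_config())
  s <- delusim:::normalize(runif(72))
  expect_equal(expected_free_energy(m, s, 1, 3), 0)
})

test_that("policy distributions combine habits, evidence and precision", {
  pd <- policy_distributions(G = c(0, 0), F = c(0, 0), e = c(1, 1), gamma = 1)
  expect_equal(pd$pi0, c(0.5, 0.5))
  expect_equal(pd$pi, c(0.5, 0.5))
  ## direct softmax evaluation
  pd <- policy_distributions(G = c(0, 1), F = c(0, 0), e = c(1, 1), gamma = 1)
  expect_equal(pd$pi, c(0.731, 0.269), tolerance = 1e-3)
  ## habit resistance: large flat counts leave pi0 ~ softmax(-gamma G)
  e <- c(599 + 250, 599, 599, 599)
  pd <- policy_distributions(G = c(1, 0, 0, 0), F = rep(0, 4), e = e,
                             gamma = 1)
  ref <- softmax(-c(1, 0, 0, 0))
  expect_lt(max(abs(pd$pi0 - ref)), 0.1)
  ## gamma scales the habit log-prior: at gamma = 2 log-odds double
  pd2 <- policy_distributions(G = c(0, 0), F = c(0, 0), e = c(4, 1),
                              gamma = 2)
  expect_equal(pd2$pi0[1] / pd2$pi0[2], 16, tolerance = 1e-9)
  pd1 <- policy_distributions(G = c(0, 0), F = c(0, 0), e = c(4, 1),
                              gamma = 2, scale_habit = FALSE)
  expect_equal(pd1$pi0[1] / pd1$pi0[2], 4, tolerance = 1e-9)
})

test_that("precision updates follow the innovation arithmetic", {
  ## hand-computed: beta' = 1 + (0.3*1 + (-0.3)*2) = 0.7
  up <- update_precision(1, pi = c(0.8, 0.2), pi0 = c(0.5, 0.5), G = c(1, 2))
  expect_equal(up$beta_posterior, 0.7)
  expect_equal(up$gamma, 1 / 0.7)
  ## zero innovation when posterior equals prior
  up <- update_precision(1.3, pi = c(0.4, 0.6), pi0 = c(0.4, 0.6),
                         G = c(5, -2))
  expect_equal(up$beta_posterior, 1.3)
  ## mass moving toward the lowest-G policy raises gamma
  up <- update_precision(1, pi = c(0.9, 0.1), pi0 = c(0.5, 0.5), G = c(-1, 1))
  expect_gt(up$gamma, 1)
  ## floored at a small positive value
  up <- update_precision(0.01, pi = c(1, 0), pi0 = c(0, 1), G = c(-50, 50))
  expect_gt(up$beta_posterior, 0)
})

test_that("Bayesian model averaging weights policy posteriors", {
  expect_equal(bma_states(list(c(0.2, 0.8)), pi = 1), c(0.2, 0.8))
  expect_equal(bma_states(list(c(1, 0), c(0, 1)), pi = c(0.5, 0.5)),
               c(0.5, 0.5))
  ## three-policy toy case against direct evaluation
  ps <- list(c(0.1, 0.9), c(0.5, 0.5), c(0.9, 0.1))
  w <- c(0.2, 0.3, 0.5)
  expect_equal(bma_states(ps, w),
               0.2 * ps[[1]] + 0.3 * ps[[2]] + 0.5 * ps[[3]])
  ## factor-list posteriors are averaged elementwise
  fl <- list(list(x = c(1, 0)), list(x = c(0, 1)))
  expect_equal(bma_states(fl, c(0.25, 0.75))$x, c(0.25, 0.75))
})

test_that("action sampling marginalizes policies and respects alpha", {
  pol <- c("trust", "trust", "distrust", "distrust")
  sa <- select_action(c(0.3, 0.3, 0.2, 0.2), pol, alpha = 1)
  expect_equal(unname(sa$p_marginal["trust"]), 0.6)
  ## alpha = 1 reproduces the marginal: Monte-Carlo within 3 SE
  set.seed(2)
  n <- 10000
  draws <- replicate(n, select_action(c(0.3, 0.3, 0.2, 0.2), pol, 1)$action)
  expect_lt(abs(mean(draws == "trust") - 0.6), 3 * sqrt(0.24 / n))
  ## large alpha approaches the argmax action
  draws <- replicate(300, select_action(c(0.45, 0.45, 0.05, 0.05), pol,
                                        alpha = 50)$action)
  expect_true(all(draws == "trust"))
})

test_that("habit counts accumulate the policy posterior and never decrease", {
  e <- c(2, 2, 2, 2)
  expect_equal(update_habits(e, c(1, 0, 0, 0)), c(3, 2, 2, 2))
  expect_equal(update_habits(e, rep(0.25, 4)), rep(2.25, 4))
  set.seed(1)
  for (i in 1:20) {
    pi <- delusim:::normalize(runif(4))
    e2 <- update_habits(e, pi)
    expect_true(all(e2 >= e))
    e <- e2
  }
})
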