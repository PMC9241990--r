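# synthetic trial records with chosen posteriors and realized intentions
fake_records <- function(posterior_trust, true_intention) {
  data.frame(
    trial = seq_along(posterior_trust),
    true_intention = true_intention,
    posterior_trust = posterior_trust
  )
}

test_that("false inferences are wrong-side posteriors, strictly", {
  r <- fake_records(c(0.6, 0.5, 0.4, 0.9), c(2L, 2L, 2L, 1L))
  expect_equal(flag_false_inferences(r), c(TRUE, FALSE, FALSE, FALSE))
  ## all posteriors on the correct side: no flags
  r <- fake_records(c(0.9, 0.1, 0.8), c(1L, 2L, 1L))
  expect_equal(sum(flag_false_inferences(r)), 0)
})

test_that("delusion score sums falsity, certainty and incorrigibility", {
  ## flags (T, T, F, F) with false-state posteriors 0.8 and 0.9
  r <- fake_records(c(0.8, 0.9, 0.9, 0.1), c(2L, 2L, 1L, 2L))
  d <- delusion_score(r)
  expect_equal(d$falsity, 0.5)
  expect_equal(d$certainty, 0.85)
  expect_equal(d$incorrigibility, 0.5)
  expect_equal(d$delusion_score, 1.85)
  ## zero flags give score zero; certain persistent falsity gives three
  expect_equal(delusion_score(fake_records(c(0.9, 0.9), c(1L, 1L)))$delusion_score, 0)
  d3 <- delusion_score(fake_records(rep(1, 5), rep(2L, 5)))
  expect_equal(d3$delusion_score, 3)
  ## a flagged final trial leaves the incorrigibility denominator
  r <- fake_records(c(0.9, 0.1, 0.9), c(2L, 2L, 2L))
  expect_equal(delusion_score(r)$incorrigibility, 0) # only trial 1 counts
})

test_that("falsity and certainty ignore trial order; incorrigibility does not", {
  set.seed(3)
  post <- runif(40)
  truth <- sample(1:2, 40, replace = TRUE)
  r <- fake_records(post, truth)
  perm <- sample(40)
  rp <- fake_records(post[perm], truth[perm])
  d <- delusion_score(r); dp <- delusion_score(rp)
  expect_equal(d$falsity, dp$falsity)
  expect_equal(d$certainty, dp$certainty)
})

test_that("delusion classification applies strict, kind-specific thresholds", {
  mk <- function(falsity, confs, incorr) {
    list(falsity = falsity, confidences = confs, incorrigibility = incorr,
         n_false = length(confs))
  }
  ## all three comfortably exceeded
  comp <- mk(0.40, rep(0.95, 40), 0.9)
  expect_true(classify_delusion(comp, "changing_trustworthiness", 66))
  expect_false(classify_delusion(comp, "consistently_trustworthy", 66))
  ## components exactly at threshold fail (strict >)
  comp <- mk(0.66, rep(0.95, 40), 0.9)
  expect_false(classify_delusion(comp, "consistently_trustworthy", 66))
  comp <- mk(0.7, rep(0.95, 40), 0.66)
  expect_false(classify_delusion(comp, "consistently_trustworthy", 66))
  ## confidence must exceed 0.8 on more than the threshold share
  comp <- mk(0.7, c(rep(0.81, 60), rep(0.79, 40)), 0.9)
  expect_false(classify_delusion(comp, "consistently_trustworthy", 66))
  comp <- mk(0.7, c(rep(0.81, 70), rep(0.79, 30)), 0.9)
  expect_true(classify_delusion(comp, "consistently_trustworthy", 66))
})

test_that("threshold variants nest monotonically", {
  set.seed(7)
  for (kind in c("consistently_trustworthy", "changing_trustworthiness")) {
    for (i in 1:40) {
      comp <- list(falsity = runif(1), confidences = runif(sample(1:30, 1)),
                   incorrigibility = runif(1))
      comp$n_false <- length(comp$confidences)
      d70 <- classify_delusion(comp, kind, 70)
      d66 <- classify_delusion(comp, kind, 66)
      d60 <- classify_delusion(comp, kind, 60)
      expect_true(d66 || !d70)
      expect_true(d60 || !d66)
    }
  }
})

test_that("habit strength is the absolute log trust/distrust ratio", {
  expect_equal(habit_strength(c(2, 2, 2, 2)), 0)
  expect_equal(habit_strength(c(2, 2, 1, 1)), log(2))
  expect_equal(habit_strength(c(1, 1, 2, 2)), log(2)) # symmetric
  expect_equal(habit_strength(c(4, 2)), log(2))       # totals directly
})

test_that("habit-based delusion flags follow the final count margins", {
  ## 0.8 trust marginal: advisor flag on the changing kind
  fl <- classify_habit_delusion(c(4, 4, 1, 1), "changing_trustworthiness")
  expect_true(fl$advisor); expect_false(fl$card)
  ## 0.51 distrust marginal flags only on the consistently-trustworthy kind
  e <- c(0.49, 0.49, 0.51, 0.51) * 10
  expect_false(classify_habit_delusion(e, "changing_trustworthiness")$advisor)
  expect_true(classify_habit_delusion(e, "consistently_trustworthy")$advisor)
  ## uniform counts raise nothing
  fl <- classify_habit_delusion(c(3, 3, 3, 3), "consistently_trustworthy")
  expect_false(fl$advisor); expect_false(fl$card)
  ## 0.8 card marginal flags the card
  fl <- classify_habit_delusion(c(8, 2, 8, 2), "changing_trustworthiness")
  expect_true(fl$card); expect_false(fl$advisor)
})

test_that("decile trajectories average agents sorted by falsity", {
  mk_run <- function(post, truth, gamma, et, ed) {
    structure(list(records = data.frame(
      trial = seq_along(post), true_intention = truth,
      posterior_trust = post, gamma_T = gamma, e_trust = et, e_distrust = ed
    )), class = "agent_run")
  }
  expect_error(trajectory_summary(list(mk_run(0.5, 1L, 1, 1, 1))), "10")
  ## twenty synthetic agents with known falsity ordering
  set.seed(5)
  runs <- lapply(1:20, function(i) {
    n <- 30
    post <- rep(1 - i / 40, n) # higher i = lower posterior on trustworthy
    mk_run(post, rep(1L, n), gamma = rep(i, n),
           et = seq_len(n) + i, ed = rep(1, n))
  })
  traj <- trajectory_summary(runs)
  expect_equal(sort(unique(traj$decile)), 1:10)
  expect_equal(sort(unique(traj$variable)),
               c("cum_belief_change", "gamma", "habit_strength"))
  ## decile means of gamma match direct averaging over the sorted pairs
  falsity <- vapply(runs, function(r) mean(flag_false_inferences(r)), 0)
  ord <- order(falsity)
  g1 <- traj$value[traj$decile == 1 & traj$variable == "gamma" &
                     traj$trial == 1]
  expect_equal(g1, mean(vapply(runs[ord[1:2]],
                               function(r) r$records$gamma_T[1], 0)))
  ## constant posteriors give zero cumulative belief change
  cbc <- traj$value[traj$variable == "cum_belief_change" & traj$trial == 30]
  expect_true(all(cbc == 0))
})

test_that("assess_agent bundles the per-run metrics coherently", {
  run <- run_agent(agent_config(a = 0.9, e0 = 600, seed = 2),
                   make_sequence("consistently_trustworthy", seed = 2),
                   n_trials = 40)
  a <- assess_agent(run)
  expect_equal(a$delusion_score,
               a$falsity + a$certainty + a$incorrigibility)
  expect_false(a$is_delusion_main)
  expect_equal(a$habit_strength,
               abs(log(sum(run$final_e[1:2]) / sum(run$final_e[3:4]))))
  expect_equal(a$proportion_correct, mean(run$records$correct))
})
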