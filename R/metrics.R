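## Scoring of agent runs: false inferences, the three-part delusion score,
## delusion classification, habit strength and habit-based classification,
## and state-space trajectory summaries across agents.

#' Flag false inferences
#'
#' A trial is a false inference when the agent's final posterior assigns
#' strictly more than 50% to the wrong realized trustworthiness state,
#' i.e. the posterior probability of the realized intention is < 0.5
#' (a posterior of exactly 0.5 is not flagged).
#'
#' @param records Trial records (the `records` data.frame of an
#'   [run_agent()] result, or an `agent_run`).
#' @return Logical vector, one flag per trial.
#' @export
flag_false_inferences <- function(records) {
  if (inherits(records, "agent_run")) records <- records$records
  p_realized <- ifelse(records$true_intention == 1L,
                       records$posterior_trust, 1 - records$posterior_trust)
  p_realized < 0.5
}

#' Delusion score of a run
#'
#' The delusion score (0 to 3) sums three components: `falsity`, the
#' proportion of trials with a false trustworthiness inference; `certainty`,
#' the mean confidence of those false inferences (the posterior probability
#' placed on the wrongly believed state; 0 when there are none); and
#' `incorrigibility`, the proportion of false inferences followed by another
#' false inference on the next trial (a flagged final trial, whose successor
#' is undefined, is excluded from the denominator).
#'
#' @param records Trial records or an `agent_run`.
#' @param false_flags Optional precomputed [flag_false_inferences()] output.
#' @return List with `falsity`, `certainty`, `incorrigibility`,
#'   `delusion_score`, `n_false`, `n_trials`, and `confidences` (per flagged
#'   trial).
#' @export
delusion_score <- function(records, false_flags = flag_false_inferences(records)) {
  if (inherits(records, "agent_run")) records <- records$records
  n <- nrow(records)
  stopifnot(n >= 1, length(false_flags) == n)
  p_realized <- ifelse(records$true_intention == 1L,
                       records$posterior_trust, 1 - records$posterior_trust)
  conf <- 1 - p_realized[false_flags]
  falsity <- mean(false_flags)
  certainty <- if (length(conf)) mean(conf) else 0
  idx <- which(false_flags)
  idx_with_next <- idx[idx < n]
  incorr <- if (length(idx_with_next)) {
    mean(false_flags[idx_with_next + 1L])
  } else 0
  list(
    falsity = falsity,
    certainty = certainty,
    incorrigibility = incorr,
    delusion_score = falsity + certainty + incorr,
    n_false = sum(false_flags),
    n_trials = n,
    confidences = conf
  )
}

#' Classify a run as delusional
#'
#' All three criteria must be strictly exceeded: (i) falsity: more than 66%
#' of inferences false on the consistently-trustworthy sequence, halved to
#' 33% on the changing-trustworthiness sequences (a fixed delusion can be
#' wrong on at most half of those trials); (ii) certainty: more than 66% of
#' false inferences held with more than 80% confidence; (iii)
#' incorrigibility: more than 66% of false inferences followed by another.
#' Sensitivity variants replace 66% with 60% or 70% in all three criteria
#' (the changing-kind falsity threshold being half of that).
#'
#' @param components A [delusion_score()] result.
#' @param sequence_kind `"consistently_trustworthy"` or
#'   `"changing_trustworthiness"`.
#' @param threshold_variant 66 (main), 60 or 70.
#' @return Logical.
#' @export
classify_delusion <- function(components, sequence_kind,
                              threshold_variant = 66) {
  stopifnot(threshold_variant %in% c(60, 66, 70))
  thr <- threshold_variant / 100
  falsity_thr <- if (sequence_kind == "changing_trustworthiness") thr / 2 else thr
  if (components$falsity <= falsity_thr) return(FALSE)
  if (components$n_false == 0) return(FALSE)
  certain_prop <- mean(components$confidences > 0.8)
  certain_prop > thr && components$incorrigibility > thr
}

#' Habit strength
#'
#' `| ln(e_trust / e_distrust) |`, where `e_trust` and `e_distrust` sum the
#' Dirichlet habit counts over policies sharing the trust and distrust
#' action.
#'
#' @param e Habit counts over the four policies, or a 2-vector
#'   `c(e_trust, e_distrust)`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' habit_strength(c(2, 2, 1, 1)) # ln 2
habit_strength <- function(e) {
  stopifnot(all(e > 0))
  if (length(e) == 2L) {
    abs(log(e[1] / e[2]))
  } else {
    stopifnot(length(e) == nrow(policy_set()))
    abs(log(sum(e[TRUST_POLICIES]) / sum(e[!TRUST_POLICIES])))
  }
}

#' Classify delusion-like habit priors
#'
#' Flags, from the final Dirichlet habit counts, a delusion-like prior over
#' policies: more than 75% normalized probability of choosing one card
#' (card flag) or of one trust state over the other (advisor flag); on the
#' consistently-trustworthy sequence, a distrust probability above 50% also
#' raises the advisor flag.
#'
#' @param e_final Final habit counts over the four policies.
#' @param sequence_kind Sequence kind string.
#' @return List with logicals `card` and `advisor`.
#' @export
classify_habit_delusion <- function(e_final, sequence_kind) {
  pol <- policy_set()
  p_trust <- sum(e_final[TRUST_POLICIES]) / sum(e_final)
  p_blue <- sum(e_final[pol$card == "blue"]) / sum(e_final)
  card_flag <- p_blue > 0.75 || p_blue < 0.25
  advisor_flag <- p_trust > 0.75 || p_trust < 0.25
  if (sequence_kind == "consistently_trustworthy" && (1 - p_trust) > 0.5) {
    advisor_flag <- TRUE
  }
  list(card = card_flag, advisor = advisor_flag)
}

#' Full assessment of one run
#'
#' Convenience wrapper combining [flag_false_inferences()],
#' [delusion_score()], [classify_delusion()] at all threshold variants,
#' [habit_strength()] and [classify_habit_delusion()].
#'
#' @param run An [run_agent()] result.
#' @return List of class `delusion_assessment`.
#' @export
assess_agent <- function(run) {
  flags <- flag_false_inferences(run)
  comp <- delusion_score(run$records, flags)
  kind <- run$sequence_kind
  habit <- classify_habit_delusion(run$final_e, kind)
  structure(list(
    false_flags = flags,
    falsity = comp$falsity,
    certainty = comp$certainty,
    incorrigibility = comp$incorrigibility,
    delusion_score = comp$delusion_score,
    n_false = comp$n_false,
    is_delusion_main = classify_delusion(comp, kind, 66),
    is_delusion_60 = classify_delusion(comp, kind, 60),
    is_delusion_70 = classify_delusion(comp, kind, 70),
    habit_strength = habit_strength(run$final_e),
    card_habit_delusion = habit$card,
    advisor_habit_delusion = habit$advisor,
    proportion_correct = mean(run$records$correct)
  ), class = "delusion_assessment")
}

#' Decile state-space trajectories
#'
#' Sorts agents by their proportion of false inferences, partitions them into
#' ten deciles, and returns per-trial decile means of posterior policy
#' precision `gamma_T`, habit strength, and the cumulative trial-to-trial
#' change in the posterior trustworthiness belief.
#'
#' @param runs List of [run_agent()] results (at least 10), each with the
#'   same number of trials.
#' @return Long-format data.frame with columns `decile`, `trial`, `variable`
#'   (`gamma`, `habit_strength`, `cum_belief_change`), `value`, and
#'   `mean_falsity` per decile.
#' @export
trajectory_summary <- function(runs) {
  if (length(runs) < 10) stop("need at least 10 agents to form deciles")
  n_trials <- nrow(runs[[1]]$records)
  falsity <- vapply(runs, function(r) mean(flag_false_inferences(r)), numeric(1))
  ord <- order(falsity)
  decile <- integer(length(runs))
  decile[ord] <- ceiling(seq_along(ord) / (length(ord) / 10))
  decile[decile > 10] <- 10L

  per_agent <- lapply(runs, function(r) {
    rec <- r$records
    hs <- abs(log(rec$e_trust / rec$e_distrust))
    dpost <- c(0, abs(diff(rec$posterior_trust)))
    cbind(gamma = rec$gamma_T, habit_strength = hs,
          cum_belief_change = cumsum(dpost))
  })

  out <- list()
  for (d in 1:10) {
    members <- which(decile == d)
    if (!length(members)) next
    avg <- Reduce(`+`, per_agent[members]) / length(members)
    for (v in colnames(avg)) {
      out[[length(out) + 1L]] <- data.frame(
        decile = d, trial = seq_len(n_trials), variable = v,
        value = avg[, v], mean_falsity = mean(falsity[members])
      )
    }
  }
  do.call(rbind, out)
}

#' @export
print.delusion_assessment <- function(x, ...) {
  cat(sprintf(
    paste0("<delusion_assessment> score %.2f (falsity %.2f, certainty %.2f,",
           " incorrigibility %.2f)\n"),
    x$delusion_score, x$falsity, x$certainty, x$incorrigibility))
  cat(sprintf("  delusional (66%% thresholds): %s   habit strength: %.2f\n",
              x$is_delusion_main, x$habit_strength))
  invisible(x)
}
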