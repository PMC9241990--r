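## The simulation study: pseudorandom parameter sweeps over agent
## configurations, the simulated antipsychotic treatment, and sweep-level
## summaries (delusion frequencies, Spearman correlations, standardized
## regression with pairwise interactions).

#' Sweep specification
#'
#' Defines one simulation set: the task sequence kind, whether affect is
#' modelled, whether the treatment is applied, the number of agents, and the
#' parameter ranges from which agent configurations are drawn uniformly:
#' likelihood precision `a` in `[0.60, 0.99]`, habit resistance `e0` in
#' `[2, 600]`, initial consistency in `[1, 125]` (changing sequences), mood
#' in `[-4.5, 4.5]` (affect models), choice precision `alpha` in
#' `[0.5, 2.75]`, prior policy precision `1/beta` in `[0.25, 1.75]`.
#'
#' @param sequence_kind Task sequence kind.
#' @param affect Logical: include affect and arousal.
#' @param treatment Logical: apply the policy-precision treatment.
#' @param n_agents Number of agents (972).
#' @param master_seed Master seed; all per-agent seeds derive from it.
#' @param ranges Named list of `c(min, max)` parameter ranges (defaults as
#'   above).
#' @return List of class `sweep_spec`.
#' @export
sweep_spec <- function(sequence_kind = "changing_trustworthiness",
                       affect = TRUE, treatment = FALSE, n_agents = 972L,
                       master_seed = 1L,
                       ranges = list(
                         a = c(0.60, 0.99),
                         e0 = c(2, 600),
                         initial_consistency = c(1, 125),
                         mood = c(-4.5, 4.5),
                         alpha = c(0.5, 2.75),
                         inv_beta = c(0.25, 1.75)
                       )) {
  sequence_kind <- match.arg(sequence_kind,
                             c("consistently_trustworthy",
                               "changing_trustworthiness"))
  structure(list(sequence_kind = sequence_kind, affect = isTRUE(affect),
                 treatment = isTRUE(treatment),
                 n_agents = as.integer(n_agents),
                 master_seed = as.integer(master_seed), ranges = ranges),
            class = "sweep_spec")
}

#' The five canonical simulation sets
#'
#' Set 1: no affect, consistently trustworthy. Set 2: affect, consistently
#' trustworthy. Set 3: no affect, changing trustworthiness. Set 4: affect,
#' changing trustworthiness. Set 5: as set 4 with the policy-precision
#' treatment.
#'
#' @param set Integer 1 to 5.
#' @param n_agents,master_seed Passed to [sweep_spec()].
#' @return A [sweep_spec()].
#' @export
simulation_set <- function(set, n_agents = 972L, master_seed = 1L) {
  stopifnot(set %in% 1:5)
  args <- switch(set,
    list(sequence_kind = "consistently_trustworthy", affect = FALSE),
    list(sequence_kind = "consistently_trustworthy", affect = TRUE),
    list(sequence_kind = "changing_trustworthiness", affect = FALSE),
    list(sequence_kind = "changing_trustworthiness", affect = TRUE),
    list(sequence_kind = "changing_trustworthiness", affect = TRUE,
         treatment = TRUE)
  )
  do.call(sweep_spec, c(args, list(n_agents = n_agents,
                                   master_seed = master_seed)))
}

#' Sample agent configurations for a sweep
#'
#' Draws each parameter independently and uniformly from its range. Mood is
#' drawn only for affect models and initial consistency only for changing
#' sequences. Per-agent seeds (for both the agent and its task sequence) are
#' derived deterministically from the master seed, so a sweep is fully
#' reproducible.
#'
#' @param spec A [sweep_spec()].
#' @return Data frame with one row per agent: sampled parameters plus
#'   `agent_seed` and `sequence_seed`.
#' @export
sample_parameters <- function(spec) {
  n <- spec$n_agents
  rg <- spec$ranges
  with_seed(spec$master_seed, {
    df <- data.frame(
      agent = seq_len(n),
      a = stats::runif(n, rg$a[1], rg$a[2]),
      e0 = stats::runif(n, rg$e0[1], rg$e0[2]),
      alpha = stats::runif(n, rg$alpha[1], rg$alpha[2]),
      inv_beta = stats::runif(n, rg$inv_beta[1], rg$inv_beta[2])
    )
    df$mood <- if (spec$affect) {
      stats::runif(n, rg$mood[1], rg$mood[2])
    } else 0
    df$initial_consistency <- if (spec$sequence_kind == "changing_trustworthiness") {
      sample(seq(rg$initial_consistency[1], rg$initial_consistency[2]), n,
             replace = TRUE)
    } else NA_integer_
    df$agent_seed <- sample.int(.Machine$integer.max - 1L, n)
    df$sequence_seed <- sample.int(.Machine$integer.max - 1L, n)
    df
  })
}

#' Simulated antipsychotic treatment of policy precision
#'
#' Once an agent has accumulated `threshold` (10) false inferences, its
#' policy precision prior is reduced once, permanently, according to
#' `1/beta* = (1/beta - min_inv_beta) * 0.5 + min_inv_beta`, where
#' `min_inv_beta` = 0.25 is the population minimum of the sampled `1/beta`
#' range: large precisions are halved towards the floor, the floor itself is
#' a fixed point.
#'
#' @param inv_beta_current Current `1/beta`.
#' @param n_false_so_far Cumulative number of false inferences.
#' @param threshold Trigger count (10).
#' @param min_inv_beta Population minimum of `1/beta` (0.25).
#' @return The (possibly reduced) `1/beta`.
#' @export
#' @examples
#' apply_treatment(1.75, 10) # 1.00
#' apply_treatment(0.25, 10) # 0.25, the fixed point
apply_treatment <- function(inv_beta_current, n_false_so_far,
                            threshold = 10, min_inv_beta = 0.25) {
  if (n_false_so_far < threshold) return(inv_beta_current)
  (inv_beta_current - min_inv_beta) * 0.5 + min_inv_beta
}

#' Treatment hook specification
#'
#' @param threshold False inferences before treatment onset.
#' @param min_inv_beta Population minimum of `1/beta`.
#' @return List passed as `treatment` to [run_agent()].
#' @export
treatment_spec <- function(threshold = 10, min_inv_beta = 0.25) {
  list(threshold = threshold, min_inv_beta = min_inv_beta)
}

#' Run a parameter sweep
#'
#' Runs every sampled agent through the task, scores it, and computes
#' sweep-level summaries: delusion frequencies at the 66% (and 60%, 70%)
#' thresholds, Spearman correlations of each parameter with delusion score
#' and with the proportion of correct card choices (absolute mood is used for
#' changing-trustworthiness sweeps), and a least-squares regression of
#' delusion score on standardized parameters plus all pairwise interactions.
#'
#' Consistently-trustworthy sweeps share a single scheduled sequence of
#' correct cards across agents; changing sweeps draw a per-agent sequence
#' because each agent has its own initial consistency.
#'
#' Individual agent failures are caught and excluded; the sweep aborts if
#' more than 1% of agents fail.
#'
#' @param spec A [sweep_spec()].
#' @param n_trials Trials per agent (250).
#' @param keep_trajectories Keep slim per-trial trajectories (needed for
#'   [trajectory_summary()] over the sweep).
#' @param progress Print a progress line every 100 agents.
#' @return Object of class `sweep_result`: list with `agents` (per-agent data
#'   frame), `summary`, `spec`, and optionally `trajectories`.
#' @export
run_sweep <- function(spec, n_trials = 250L, keep_trajectories = FALSE,
                      progress = FALSE, opts = scheme_options()) {
  params <- sample_parameters(spec)
  n <- nrow(params)
  treatment <- if (spec$treatment) treatment_spec() else NULL
  changing <- spec$sequence_kind == "changing_trustworthiness"
  shared_seq <- if (!changing) {
    make_sequence("consistently_trustworthy", seed = spec$master_seed,
                  n_trials = n_trials)
  }
  rows <- vector("list", n)
  traj <- if (keep_trajectories) vector("list", n)
  failures <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      cfg <- agent_config(a = params$a[i], e0 = params$e0[i],
                          mood = params$mood[i], alpha = params$alpha[i],
                          inv_beta = params$inv_beta[i], affect = spec$affect,
                          seed = params$agent_seed[i])
      seqn <- if (changing) {
        make_sequence("changing_trustworthiness",
                      initial_consistency = params$initial_consistency[i],
                      seed = params$sequence_seed[i], n_trials = n_trials)
      } else shared_seq
      run <- run_agent(cfg, seqn, n_trials = n_trials, treatment = treatment,
                       opts = opts)
      list(run = run, ass = assess_agent(run))
    }, error = function(err) err)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > max(1, ceiling(0.01 * n))) {
        stop("more than 1% of agents failed; last error: ",
             conditionMessage(res))
      }
      warning(sprintf("agent %d failed and was excluded: %s", i,
                      conditionMessage(res)), call. = FALSE)
      next
    }
    ass <- res$ass
    rows[[i]] <- data.frame(
      params[i, , drop = FALSE],
      proportion_correct = ass$proportion_correct,
      n_false = ass$n_false,
      falsity = ass$falsity, certainty = ass$certainty,
      incorrigibility = ass$incorrigibility,
      delusion_score = ass$delusion_score,
      is_delusion_main = ass$is_delusion_main,
      is_delusion_60 = ass$is_delusion_60,
      is_delusion_70 = ass$is_delusion_70,
      habit_strength = ass$habit_strength,
      card_habit_delusion = ass$card_habit_delusion,
      advisor_habit_delusion = ass$advisor_habit_delusion,
      treated = !is.na(res$run$treated_at)
    )
    if (keep_trajectories) {
      rec <- res$run$records
      traj[[i]] <- structure(
        list(records = rec[, c("gamma_T", "e_trust", "e_distrust",
                               "posterior_trust", "true_intention")]),
        class = "agent_run")
    }
    if (progress && i %% 100 == 0) {
      message(sprintf("  agent %d/%d", i, n))
    }
  }
  agents <- do.call(rbind, rows)
  out <- structure(list(
    spec = spec,
    agents = agents,
    n_failed = failures,
    summary = summarize_sweep(agents, spec)
  ), class = "sweep_result")
  if (keep_trajectories) out$trajectories <- Filter(Negate(is.null), traj)
  out
}

## Sweep-level summaries: frequencies, Spearman correlations, regression.
summarize_sweep <- function(agents, spec) {
  changing <- spec$sequence_kind == "changing_trustworthiness"
  preds <- c("a", "e0", "alpha", "inv_beta")
  if (spec$affect) {
    agents$mood_col <- if (changing) abs(agents$mood) else agents$mood
    preds <- c(preds, "mood_col")
  }
  if (changing) preds <- c(preds, "initial_consistency")

  rho <- function(x, y) {
    suppressWarnings(stats::cor(x, y, method = "spearman"))
  }
  spearman <- data.frame(
    parameter = sub("mood_col", if (changing) "abs_mood" else "mood", preds),
    rho_delusion_score = vapply(preds, function(p) {
      rho(agents[[p]], agents$delusion_score)
    }, numeric(1)),
    rho_proportion_correct = vapply(preds, function(p) {
      rho(agents[[p]], agents$proportion_correct)
    }, numeric(1)),
    row.names = NULL
  )

  ## standardized regression with all pairwise interactions; degenerate when
  ## no agent scores above zero (e.g. the no-affect consistent sweep)
  if (stats::sd(agents$delusion_score) > 0) {
    Z <- as.data.frame(scale(agents[preds]))
    names(Z) <- sub("mood_col", "abs_mood", names(Z))
    Z$delusion_score <- as.vector(scale(agents$delusion_score))
    fit <- stats::lm(delusion_score ~ (.)^2, data = Z)
    coefs <- summary(fit)$coefficients
    regression <- data.frame(
      term = rownames(coefs),
      beta = coefs[, "Estimate"],
      p_value = coefs[, "Pr(>|t|)"],
      significant = coefs[, "Pr(>|t|)"] < 0.05,
      row.names = NULL
    )
    regression <- regression[regression$term != "(Intercept)", ]
  } else {
    regression <- data.frame(term = character(), beta = numeric(),
                             p_value = numeric(), significant = logical())
  }

  list(
    n_agents = nrow(agents),
    delusion_frequency = c(
      main_66 = mean(agents$is_delusion_main),
      alt_60 = mean(agents$is_delusion_60),
      alt_70 = mean(agents$is_delusion_70)
    ),
    n_delusional = c(
      main_66 = sum(agents$is_delusion_main),
      alt_60 = sum(agents$is_delusion_60),
      alt_70 = sum(agents$is_delusion_70)
    ),
    n_with_false_inference = sum(agents$n_false > 0),
    habit_delusion_frequency = c(
      card = mean(agents$card_habit_delusion),
      advisor = mean(agents$advisor_habit_delusion)
    ),
    spearman = spearman,
    regression = regression
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sweep_result> %s%s, n = %d agents\n", x$spec$sequence_kind,
              paste0(if (x$spec$affect) ", affect" else ", no affect",
                     if (x$spec$treatment) ", treated" else ""),
              s$n_agents))
  cat(sprintf("  delusions: %.1f%% (60%%: %.1f%%, 70%%: %.1f%%)   agents with false inferences: %d\n",
              100 * s$delusion_frequency[["main_66"]],
              100 * s$delusion_frequency[["alt_60"]],
              100 * s$delusion_frequency[["alt_70"]],
              s$n_with_false_inference))
  cat("  Spearman rho vs delusion score:\n")
  for (i in seq_len(nrow(s$spearman))) {
    cat(sprintf("    %-20s %+ .3f\n", s$spearman$parameter[i],
                s$spearman$rho_delusion_score[i]))
  }
  invisible(x)
}

#' Write sweep reports
#'
#' Writes a summary (JSON and CSV of the Spearman table and regression), the
#' per-agent CSV, and, when trajectories were kept, the decile trajectory
#' CSV, into `out_dir`. Seeds and package version are logged in the JSON for
#' reproducibility.
#'
#' @param result A [run_sweep()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
report_sweep <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- result$summary
  freq_pct <- sprintf("%.1f%%", 100 * s$delusion_frequency)
  names(freq_pct) <- names(s$delusion_frequency)
  summary_json <- list(
    sequence_kind = result$spec$sequence_kind,
    affect = result$spec$affect,
    treatment = result$spec$treatment,
    n_agents = s$n_agents,
    n_failed = result$n_failed,
    master_seed = result$spec$master_seed,
    package_version = as.character(utils::packageVersion("delusim")),
    delusion_frequency = as.list(s$delusion_frequency),
    delusion_frequency_pct = as.list(freq_pct),
    n_delusional = as.list(s$n_delusional),
    n_with_false_inference = s$n_with_false_inference,
    habit_delusion_frequency = as.list(s$habit_delusion_frequency)
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(s$spearman, file.path(out_dir, "spearman.csv"),
                   row.names = FALSE)
  utils::write.csv(s$regression, file.path(out_dir, "regression.csv"),
                   row.names = FALSE)
  utils::write.csv(result$agents, file.path(out_dir, "agents.csv"),
                   row.names = FALSE)
  if (!is.null(result$trajectories)) {
    utils::write.csv(trajectory_summary(result$trajectories),
                     file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
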