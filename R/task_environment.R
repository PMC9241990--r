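## The synthetic task: trustworthiness schedules, per-trial realization of the
## advisor's intention and advice, noisy feedback, and arousal outcomes.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a task sequence
#'
#' Builds the 250-trial schedule of advisor intentions and correct cards.
#' In the `consistently_trustworthy` sequence the advisor is scheduled
#' trustworthy on every trial. In the `changing_trustworthiness` sequence the
#' schedule is 125 untrustworthy then 125 trustworthy trials; the
#' `initial_consistency` rotation removes `125 - initial_consistency`
#' untrustworthy trials from the end of the first block and appends them at
#' the end, so the scheduled untrustworthy count is always 125. Correct cards
#' are independent uniform draws each trial. The sequence is a pure function
#' of `(kind, initial_consistency, seed)`.
#'
#' @param kind `"consistently_trustworthy"` or `"changing_trustworthiness"`.
#' @param initial_consistency Integer in `[1, 125]`: number of untrustworthy
#'   trials at the start of the changing sequence. Ignored for the consistent
#'   kind.
#' @param seed Integer seed for the correct-card draws.
#' @param n_trials Number of trials (250).
#' @return An object of class `task_sequence` with elements
#'   `scheduled_intention` (1 = trustworthy, 2 = untrustworthy) and
#'   `correct_card` (1 = blue, 2 = green).
#' @export
#' @examples
#' s <- make_sequence("changing_trustworthiness", initial_consistency = 50, seed = 1)
#' table(s$scheduled_intention)
make_sequence <- function(kind = c("consistently_trustworthy",
                                   "changing_trustworthiness"),
                          initial_consistency = 125L, seed = 1L,
                          n_trials = 250L) {
  kind <- match.arg(kind)
  n_trials <- as.integer(n_trials)
  half <- n_trials %/% 2L
  if (kind == "changing_trustworthiness") {
    initial_consistency <- as.integer(initial_consistency)
    if (is.na(initial_consistency) || initial_consistency < 1L ||
        initial_consistency > half) {
      stop("initial_consistency must lie in [1, ", half, "]", call. = FALSE)
    }
    scheduled <- c(rep(2L, initial_consistency), rep(1L, half),
                   rep(2L, half - initial_consistency))
  } else {
    scheduled <- rep(1L, n_trials)
    initial_consistency <- NA_integer_
  }
  cards <- with_seed(seed, sample(1:2, n_trials, replace = TRUE))
  structure(list(
    n_trials = n_trials,
    kind = kind,
    initial_consistency = initial_consistency,
    scheduled_intention = scheduled,
    correct_card = cards,
    seed = as.integer(seed)
  ), class = "task_sequence")
}

#' @export
print.task_sequence <- function(x, ...) {
  cat(sprintf("<task_sequence> %s, %d trials, %d scheduled untrustworthy%s\n",
              x$kind, x$n_trials, sum(x$scheduled_intention == 2L),
              if (is.na(x$initial_consistency)) ""
              else sprintf(", initial consistency %d", x$initial_consistency)))
  invisible(x)
}

#' @export
as.data.frame.task_sequence <- function(x, ...) {
  data.frame(
    trial = seq_len(x$n_trials),
    scheduled_intention = FACTOR_LEVELS$intention[x$scheduled_intention],
    correct_card = FACTOR_LEVELS$card[x$correct_card]
  )
}

#' Realize one trial's advisor intention and advice
#'
#' The true intention flips away from the scheduled one with probability 0.1,
#' once, at trial start. Advice is then deterministic: the correct card under
#' a trustworthy advisor, the other card otherwise. Draws use the current RNG
#' state.
#'
#' @param sequence A [make_sequence()] object.
#' @param trial_index Trial number, in `[1, n_trials]`.
#' @param flip_prob Per-trial intention flip probability (0.1).
#' @return List with `true_intention` and `advice` (level indices).
#' @export
realize_trial <- function(sequence, trial_index, flip_prob = 0.1) {
  stopifnot(trial_index >= 1, trial_index <= sequence$n_trials)
  sched <- sequence$scheduled_intention[trial_index]
  true_int <- if (stats::runif(1) < flip_prob) 3L - sched else sched
  card <- sequence$correct_card[trial_index]
  advice <- if (true_int == 1L) card else 3L - card
  list(true_intention = true_int, advice = advice)
}

#' Emit feedback for a card choice
#'
#' Feedback equals the truthful label ('correct' iff the choice matches the
#' correct card) with probability `reliability` = 0.9.
#'
#' @param choice,correct_card Card level indices (1 = blue, 2 = green).
#' @param reliability True feedback reliability.
#' @return 1 for 'correct', 2 for 'incorrect'.
#' @export
emit_feedback <- function(choice, correct_card, reliability = 0.9) {
  truthful <- choice == correct_card
  honest <- stats::runif(1) < reliability
  if (truthful == honest) 1L else 2L
}

#' Emit an arousal outcome from an affect state
#'
#' Deterministic readout: calm gives low arousal, angry gives high.
#'
#' @param affect_state 1 = calm, 2 = angry.
#' @return 1 for 'low', 2 for 'high'.
#' @export
emit_arousal <- function(affect_state) {
  stopifnot(affect_state %in% 1:2)
  as.integer(affect_state)
}

## Sample the next true affect state given the realized trust action (Eq. 5
## columns: calm twice as likely under trust).
transition_affect <- function(b_affect, trust_action, current_affect) {
  p <- b_affect[[trust_action]][, current_affect]
  sample_index(p)
}
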