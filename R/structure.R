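## Hidden-state factor and outcome-modality layout of the advisor/card task.
##
## Five hidden-state factors, evolving over the three timesteps of a trial:
##   1 intention: advisor trustworthy / untrustworthy        (2 levels)
##   2 card:      correct card blue / green                  (2)
##   3 decision:  agent's card decision null / blue / green  (3)
##   4 affect:    calm / angry                               (2)
##   5 stage:     start / advice / feedback                  (3)
## Joint state space: 2*2*3*2*3 = 72 states, vectorized column-major with
## factor 1 varying fastest.
##
## Four outcome modalities:
##   1 advice:   null / blue / green   (emitted at the advice stage)
##   2 feedback: correct / incorrect / null
##   3 arousal:  low / high            (only when affect is modelled)
##   4 choice:   null / blue / green   (proprioceptive copy of the decision)

FACTOR_LEVELS <- list(
  intention = c("trustworthy", "untrustworthy"),
  card      = c("blue", "green"),
  decision  = c("null", "blue", "green"),
  affect    = c("calm", "angry"),
  stage     = c("start", "advice", "feedback")
)

MODALITY_LEVELS <- list(
  advice   = c("null", "blue", "green"),
  feedback = c("correct", "incorrect", "null"),
  arousal  = c("low", "high", "null"),
  choice   = c("null", "blue", "green")
)

FACTOR_DIMS <- vapply(FACTOR_LEVELS, length, integer(1))
N_JOINT <- prod(FACTOR_DIMS) # 72

## Data frame with one row per joint state, columns = factor level indices.
joint_grid <- function() {
  do.call(expand.grid, lapply(FACTOR_DIMS, seq_len))
}

## The four whole-trial policies: {trust, distrust} x {choose blue, choose
## green}.  The card action is enacted at the final transition only; the
## trust/distrust control applies to every transition (it is a mental action,
## revisable until the final timestep).
policy_set <- function() {
  data.frame(
    trust = rep(c("trust", "distrust"), each = 2),
    card  = rep(c("blue", "green"), times = 2),
    stringsAsFactors = FALSE
  )
}

#' @export
print.delusim_model <- function(x, ...) {
  cat("<delusim generative model>\n")
  cat(sprintf("  likelihood precision a : %.3f\n", x$config$a))
  cat(sprintf("  habit resistance e0    : %.1f (counts: %s)\n",
              x$config$e0, paste(formatC(x$e, format = "fg"), collapse = ", ")))
  cat(sprintf("  policy precision 1/beta: %.3f   choice precision alpha: %.2f\n",
              1 / x$beta0, x$alpha))
  if (x$affect_enabled) {
    cat(sprintf("  affect: on, mood c = %.2f\n", x$config$mood))
  } else {
    cat("  affect: off\n")
  }
  cat(sprintf("  policies: %s\n",
              paste(paste(x$policies$trust, x$policies$card, sep = "/"),
                    collapse = ", ")))
  invisible(x)
}
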