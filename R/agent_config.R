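#' Agent configuration
#'
#' Bundle and validate the free parameters of one active-inference agent.
#'
#' @param a Likelihood precision: the agent's assumed reliability of card
#'   feedback, in `[0.5, 1]`. The environment's true reliability is fixed at
#'   0.9; lowering `a` makes feedback less informative to the agent.
#' @param e0 Habit resistance: the initial value of every Dirichlet habit
#'   count (one per policy). Large values (up to 600) mean newly accumulated
#'   counts barely move the policy prior; small values (2) allow fast habit
#'   formation. Must be positive.
#' @param mood Log-preference `c` for low over high arousal; negative values
#'   encode negative mood (high arousal expected). Ignored unless
#'   `affect = TRUE`.
#' @param alpha Choice precision: softmax inverse temperature over actions
#'   only. Affects behavioural stochasticity, never inference. Positive.
#' @param inv_beta Prior policy precision `1/beta`, the prior expectation of
#'   the precision `gamma` with which policies are selected. Positive.
#' @param affect Logical; whether the agent (and task) include the affect
#'   factor and arousal outcomes.
#' @param seed Integer seed for the agent's random draws.
#' @return An object of class `agent_config` (a validated list).
#' @export
#' @examples
#' agent_config(a = 0.9, e0 = 2)
agent_config <- function(a = 0.9, e0 = 2, mood = 0, alpha = 1.5,
                         inv_beta = 1, affect = FALSE, seed = 1L) {
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a < 0.5 || a > 1) {
    stop("likelihood precision `a` must lie in [0.5, 1]; values below 0.5 ",
         "would invert the meaning of feedback", call. = FALSE)
  }
  if (!is.numeric(e0) || length(e0) != 1 || is.na(e0) || e0 <= 0) {
    stop("habit resistance `e0` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0) {
    stop("choice precision `alpha` must be positive", call. = FALSE)
  }
  if (!is.numeric(inv_beta) || length(inv_beta) != 1 || is.na(inv_beta) ||
      inv_beta <= 0) {
    stop("prior policy precision `inv_beta` must be positive", call. = FALSE)
  }
  structure(
    list(a = a, e0 = e0, mood = if (isTRUE(affect)) mood else 0,
         alpha = alpha, inv_beta = inv_beta, affect = isTRUE(affect),
         seed = as.integer(seed)),
    class = "agent_config"
  )
}

#' Read an agent configuration from a flat key-value file
#'
#' The file is YAML with flat keys `a`, `e0`, `mood`, `alpha`, `inv_beta`,
#' `affect`, `seed` (any subset; missing keys take the [agent_config()]
#' defaults). Entries in `overrides` take precedence over the file, mirroring
#' command-line flag overrides.
#'
#' @param path Path to the config file, or `NULL` for defaults only.
#' @param overrides Named list of overriding values.
#' @return An [agent_config()] object.
#' @export
read_agent_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("config file must contain key: value pairs")
  }
  vals[names(overrides)] <- overrides
  known <- c("a", "e0", "mood", "alpha", "inv_beta", "affect", "seed")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(agent_config, vals)
}

#' @export
print.agent_config <- function(x, ...) {
  cat("<agent_config>",
      sprintf("a=%.3f e0=%g mood=%.2f alpha=%.2f 1/beta=%.3f affect=%s seed=%d",
              x$a, x$e0, x$mood, x$alpha, x$inv_beta, x$affect, x$seed),
      "\n")
  invisible(x)
}
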