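#' Monte Carlo simulation of the Moran chain to absorption
#'
#' Samples independent trajectories of the innovator count, stepping with
#' the exact one-step probabilities (up / down / stay) until absorption at
#' \code{0} or \code{N}, and estimates the fixation probability of the R&D
#' innovation strategy as the fraction of replicates absorbed at \code{N},
#' with the binomial standard error \eqn{\sqrt{p(1-p)/R}}. Serves as an
#' end-to-end check of the analytic engine.
#'
#' With \code{jump_chain = TRUE} the self-loop is skipped: each step
#' conditions on the count actually moving (up with probability
#' \code{up/(up+down)}). Absorption probabilities are invariant to removing
#' self-loops, so the estimator targets the same quantity, typically much
#' faster.
#'
#' @inheritParams fitness
#' @param replicates Number of independent chains, \code{>= 1}.
#' @param initial_i Starting innovator count, in \code{1..N-1}.
#' @param seed RNG seed (integer) for reproducibility; \code{NULL} leaves
#'   the RNG state alone.
#' @param max_steps Per-replicate step cap; exceeding it is an error
#'   (never silently dropped).
#' @param jump_chain Skip self-loops (see Details).
#' @return A \code{fixation_result} with \code{method = "monte_carlo"}:
#'   \code{rho_I} holds the estimated fixation probability from
#'   \code{initial_i} (the classic \eqn{\rho_I} when \code{initial_i = 1}),
#'   \code{stderr} its standard error; \code{rho_T} and \code{q} are
#'   \code{NA} (not estimated).
#' @examples
#' p <- update_params(builtin_scenarios()$fig1b, N = 8)
#' simulate_fixation(p, replicates = 2000, seed = 42)
#' @export
simulate_fixation <- function(params, replicates, initial_i = 1L, seed = NULL,
                              max_steps = 1e6, regime = "auto",
                              jump_chain = FALSE) {
  regime <- check_positive_fitness(params, regime)
  N <- params$N
  replicates <- as.integer(replicates)
  initial_i <- as.integer(initial_i)
  if (replicates < 1L)
    stop(errorCondition("invalid-parameter: replicates must be >= 1",
                        class = c("morangame_invalid_parameter", "error")))
  if (initial_i < 1L || initial_i > N - 1L)
    stop(errorCondition(
      sprintf("out-of-range: initial_i must lie in 1..%d", N - 1L),
      class = c("morangame_out_of_range", "error")))
  if (!is.null(seed)) set.seed(as.integer(seed))

  # per-state step probabilities, indexed by state 1..N-1
  up <- down <- numeric(N - 1L)
  for (i in seq_len(N - 1L)) {
    r <- transition_row(params, i, regime)
    up[i] <- r$up
    down[i] <- r$down
  }
  if (jump_chain) {
    p_up <- up / (up + down)   # conditioned on leaving the state
  }

  state <- rep(initial_i, replicates)
  active <- rep(TRUE, replicates)
  steps <- 0
  while (any(active)) {
    steps <- steps + 1
    if (steps > max_steps)
      stop(errorCondition(
        sprintf("unabsorbed-replicate: %d chain(s) not absorbed after %g steps",
                sum(active), max_steps),
        class = c("morangame_unabsorbed_replicate", "error")))
    s <- state[active]
    u <- stats::runif(length(s))
    if (jump_chain) {
      s <- ifelse(u < p_up[s], s + 1L, s - 1L)
    } else {
      s <- s + ifelse(u < up[s], 1L, ifelse(u < up[s] + down[s], -1L, 0L))
    }
    state[active] <- s
    active[active] <- s > 0L & s < N
  }
  est <- mean(state == N)
  res <- new_fixation_result(est, NA_real_, rep(NA_real_, N + 1L),
                             "monte_carlo", params, regime,
                             stderr = sqrt(est * (1 - est) / replicates))
  res$initial_i <- initial_i
  res$replicates <- replicates
  res
}
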