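# log(sum(exp(x))) without overflow; x may be any length >= 1
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' One row of the Moran transition matrix
#'
#' The innovator count follows a birth-death chain: each step one enterprise
#' is chosen to reproduce proportionally to fitness and one uniformly at
#' random to be replaced, so the count moves up or down by one or stays.
#' For interior \code{i},
#' \deqn{up = \frac{i e_{iI}}{i e_{iI} + (N-i) e_{iT}} \cdot \frac{N-i}{N},
#'   \quad down = \frac{(N-i) e_{iT}}{i e_{iI} + (N-i) e_{iT}} \cdot \frac{i}{N},}
#' and the states \code{0} and \code{N} are absorbing.
#'
#' @inheritParams fitness
#' @param i A single state in \code{0..N}.
#' @return A list with \code{i}, \code{up}, \code{down}, \code{stay}.
#' @examples
#' p <- builtin_scenarios()$fig1b
#' transition_row(p, 1)
#' @export
transition_row <- function(params, i, regime = "auto") {
  stopifnot(length(i) == 1L)
  i <- as.integer(i)
  if (i < 0L || i > params$N)
    stop(errorCondition(
      sprintf("out-of-range: state i must lie in 0..N = 0..%d", params$N),
      class = c("morangame_out_of_range", "error")))
  if (i == 0L || i == params$N)
    return(list(i = i, up = 0, down = 0, stay = 1))
  regime <- check_positive_fitness(params, regime)
  f <- fitness(params, i, regime)
  N <- params$N
  tot <- i * f$e_I + (N - i) * f$e_T
  up <- (i * f$e_I / tot) * ((N - i) / N)
  down <- ((N - i) * f$e_T / tot) * (i / N)
  list(i = i, up = up, down = down, stay = 1 - up - down)
}

#' Full (N+1) x (N+1) one-step transition matrix
#'
#' @inheritParams fitness
#' @return A dense row-stochastic matrix, rows/columns indexed by states
#'   \code{0..N}.
#' @export
transition_matrix <- function(params, regime = "auto") {
  N <- params$N
  M <- matrix(0, N + 1L, N + 1L, dimnames = list(0:N, 0:N))
  for (i in 0:N) {
    r <- transition_row(params, i, regime)
    M[i + 1L, i + 1L] <- r$stay
    if (i < N) M[i + 1L, i + 2L] <- r$up
    if (i > 0) M[i + 1L, i] <- r$down
  }
  M
}

new_fixation_result <- function(rho_I, rho_T, q, method, params, regime,
                                stderr = NULL) {
  structure(list(rho_I = rho_I, rho_T = rho_T, q = q, method = method,
                 stderr = stderr, N = params$N, regime = regime),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("Fixation probabilities (N = %d, regime = %s, method = %s)\n",
              x$N, x$regime, x$method))
  cat(sprintf("  rho_I = %.6g   N*rho_I = %.6g\n", x$rho_I, x$N * x$rho_I))
  cat(sprintf("  rho_T = %.6g   N*rho_T = %.6g\n", x$rho_T, x$N * x$rho_T))
  if (!is.null(x$stderr))
    cat(sprintf("  std. error (rho_I estimate) = %.3g\n", x$stderr))
  invisible(x)
}

#' Exact fixation probabilities by the recursive (product) formula
#'
#' Solves the absorption probabilities of the birth-death chain in closed
#' form. With \eqn{\chi_n = e_{nT}/e_{nI}} (the down/up ratio at state n),
#' \deqn{\rho_I = q_1 = \Big(1 + \sum_{k=1}^{N-1} \prod_{n=1}^{k} \chi_n\Big)^{-1},
#'   \qquad
#'   \rho_T = 1 - q_{N-1} = \Big(1 + \sum_{k=1}^{N-1} \prod_{i=k}^{N-1} \chi_i^{-1}\Big)^{-1},}
#' and \eqn{q_i} interpolates via partial sums of the same products. All
#' sums of products are accumulated as log-sum-exp over cumulative log
#' ratios, so exponential-regime runs with large \eqn{\xi E} cannot
#' overflow.
#'
#' @inheritParams fitness
#' @return A \code{fixation_result}: \code{rho_I} (probability a single
#'   innovator takes over), \code{rho_T} (probability a single
#'   non-innovator takes over), the full vector \code{q[i+1] = P(absorb at
#'   N | start at i)} for \code{i = 0..N}, and bookkeeping fields.
#' @examples
#' p <- builtin_scenarios()$fig1b
#' fixation_recursive(update_params(p, N = 4))
#' @export
fixation_recursive <- function(params, regime = "auto") {
  regime <- check_positive_fitness(params, regime)
  N <- params$N
  log_chi <- fitness_ratio_log(params, seq_len(N - 1L), regime)
  cum <- cumsum(log_chi)                  # log prod_{n=1..k} chi_n
  # q_i = (1 + sum_{k<i} e^{cum_k}) / (1 + sum_{k<N} e^{cum_k}), in log space
  log_num <- vapply(0:(N - 1L), function(i) {
    if (i == 0L) 0 else logsumexp(c(0, cum[seq_len(i)]))
  }, numeric(1))                          # numerator for q_1..q_N (i = i-1 terms)
  log_den <- log_num[N]                   # full sum, k = 1..N-1
  q <- c(0, exp(log_num - log_den))       # q_0 = 0, q_N = 1 exactly
  q[N + 1L] <- 1
  rho_I <- q[2L]
  # Eq (14) directly: reversed cumulative sums of -log_chi
  rev_cum <- rev(cumsum(rev(-log_chi)))   # log prod_{i=k..N-1} 1/chi_i
  rho_T <- stats::plogis(-logsumexp(rev_cum))
  if (is.unsorted(q, strictly = FALSE))
    warning("fixation vector q is not monotone; numerical trouble suspected")
  new_fixation_result(rho_I, rho_T, q, "recursive", params, regime)
}

#' Fixation probabilities by a tridiagonal linear solve
#'
#' Independent oracle for \code{\link{fixation_recursive}}: assembles the
#' absorption equations \eqn{q_i = down_i q_{i-1} + stay_i q_i + up_i
#' q_{i+1}} with \eqn{q_0 = 0}, \eqn{q_N = 1} as a linear system in the
#' interior unknowns and solves it directly.
#'
#' @inheritParams fitness
#' @return A \code{fixation_result} with \code{method = "linear_solve"}.
#' @export
fixation_linear_solve <- function(params, regime = "auto") {
  regime <- check_positive_fitness(params, regime)
  N <- params$N
  n <- N - 1L
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    r <- transition_row(params, i, regime)
    # row-normalized (jump-chain) form: q_i - pd*q_{i-1} - pu*q_{i+1} = 0
    # keeps the system well equilibrated under strong selection
    pu <- r$up / (r$up + r$down)
    pd <- r$down / (r$up + r$down)
    A[i, i] <- 1
    if (i > 1L) A[i, i - 1L] <- -pd
    if (i < n) A[i, i + 1L] <- -pu
    if (i == n) b[i] <- pu              # q_N = 1 boundary term
  }
  qi <- tryCatch({
    q0 <- solve(A, b)
    q0 + solve(A, b - A %*% q0)         # one step of iterative refinement
  }, error = function(e)
    stop(errorCondition(paste0("singular-system: ", conditionMessage(e)),
                        class = c("morangame_singular_system", "error"))))
  q <- c(0, qi, 1)
  new_fixation_result(q[2L], 1 - q[N], q, "linear_solve", params, regime)
}
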