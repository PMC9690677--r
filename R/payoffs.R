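#' Pairwise payoff matrix of the two strategies
#'
#' Computes the four payoffs of a pairwise encounter between the R&D
#' innovation strategy (I) and the non-R&D innovation strategy (T). An
#' innovator meeting another innovator cooperates (success rate
#' \code{eta1}) and earns \eqn{\eta_1 R_I - C_{ph}}; meeting a
#' non-innovator it researches alone (success rate \code{eta2}) and earns
#' \eqn{\eta_2 R_I - C_{ph}}. A non-innovator earns
#' \eqn{R_T - \lambda R_T - C_{pl}} regardless of its opponent: it keeps
#' the traditional revenue but pays the tax \eqn{\lambda R_T} that
#' innovators are exempted.
#'
#' @param params A \code{\link{game_params}} object.
#' @return An object of class \code{payoff_matrix}: a list with entries
#'   \code{a_II}, \code{a_IT}, \code{a_TI}, \code{a_TT} (currency units).
#' @examples
#' p <- builtin_scenarios()$fig1b
#' build_payoffs(p)  # a_II = 10, a_IT = -4, a_TI = a_TT = 2.4
#' @export
build_payoffs <- function(params) {
  stopifnot(inherits(params, "game_params"))
  validate_game_params(params)
  tax_kept <- params$RT - params$lam * params$RT - params$Cpl
  pm <- list(a_II = params$eta1 * params$RI - params$Cph,
             a_IT = params$eta2 * params$RI - params$Cph,
             a_TI = tax_kept,
             a_TT = tax_kept)
  class(pm) <- "payoff_matrix"
  pm
}

#' @export
print.payoff_matrix <- function(x, ...) {
  m <- matrix(c(x$a_II, x$a_IT, x$a_TI, x$a_TT), 2, 2, byrow = TRUE,
              dimnames = list(c("I", "T"), c("vs I", "vs T")))
  cat("Pairwise payoffs (row strategy's payoff)\n")
  print(m)
  invisible(x)
}

#' State-dependent expected revenues
#'
#' With \code{i} of the \code{N} enterprises innovating, each enterprise
#' plays against the other \code{N - 1}. The expected revenue of an
#' innovator is
#' \deqn{E_{iI} = \frac{(i-1)\,a_{II} + (N-i)\,a_{IT}}{N-1},}
#' and that of a non-innovator is \eqn{E_{iT} = a_{TT}} (constant in
#' \code{i}, because the non-innovator's payoff does not depend on its
#' opponent's strategy).
#'
#' @param params A \code{\link{game_params}} object.
#' @param i Innovator count(s), integer(s) in \code{1..N-1} (interior states
#'   only; the revenue formulas are undefined at the absorbing states).
#' @return A data frame with columns \code{i}, \code{E_I}, \code{E_T}.
#' @examples
#' p <- builtin_scenarios()$fig1b
#' expected_revenues(p, 1)        # E_I = -3.2, E_T = 2.4
#' expected_revenues(p, 1:(p$N - 1))
#' @export
expected_revenues <- function(params, i) {
  stopifnot(inherits(params, "game_params"))
  i <- as.integer(i)
  if (any(i < 1L | i > params$N - 1L))
    stop(errorCondition(
      sprintf("out-of-range: i must lie in 1..N-1 = 1..%d", params$N - 1L),
      class = c("morangame_out_of_range", "error")))
  pm <- build_payoffs(params)
  E_I <- ((i - 1) * pm$a_II + (params$N - i) * pm$a_IT) / (params$N - 1)
  data.frame(i = i, E_I = E_I, E_T = rep(pm$a_TT, length(i)))
}
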