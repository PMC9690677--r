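#' Resolve the selection regime
#'
#' Maps a regime label (or \code{"auto"}) and the selection intensity to one
#' of the three fitness maps: \code{"neutral"} (\eqn{\xi = 0}, fitness 1 for
#' everyone), \code{"linear"} (\eqn{e = 1 - \xi + \xi E}, the
#' expected-revenue regime for \eqn{0 < \xi \le 1}) and
#' \code{"exponential"} (\eqn{e = \exp(\xi E)}, the super-expected-revenue
#' regime for \eqn{\xi > 1}, available for any \eqn{\xi > 0}).
#'
#' @param params A \code{\link{game_params}} object.
#' @param regime One of \code{"auto"}, \code{"neutral"}, \code{"linear"},
#'   \code{"exponential"}.
#' @return The resolved regime label.
#' @export
resolve_regime <- function(params, regime = "auto") {
  if (!is.character(regime) || length(regime) != 1L ||
      !regime %in% c("auto", "neutral", "linear", "exponential"))
    stop(errorCondition(
      paste0("invalid-regime: ", paste(format(regime), collapse = ", ")),
      class = c("morangame_invalid_regime", "error")))
  if (regime != "auto") {
    if (regime == "neutral" && params$xi != 0)
      warning("neutral regime requested with xi > 0; payoffs are ignored")
    return(regime)
  }
  if (params$xi == 0) "neutral" else if (params$xi <= 1) "linear" else "exponential"
}

#' Fitness of the two strategies at interior states
#'
#' Applies the selected fitness map to the expected revenues of
#' \code{\link{expected_revenues}}. Log-fitness values are returned
#' alongside, so downstream products of fitness ratios can be accumulated in
#' log space (in the exponential regime the log is \eqn{\xi E} exactly, with
#' no overflow).
#'
#' Note the linear map can yield nonpositive fitness for strongly negative
#' revenues; that is legitimate for invasion analysis (which only uses
#' differences) but invalid for the Moran chain. Chain computations check
#' positivity and signal a classed error advising the exponential regime.
#'
#' @inheritParams resolve_regime
#' @param i Interior state(s), integer(s) in \code{1..N-1}.
#' @return A data frame with columns \code{i}, \code{e_I}, \code{e_T},
#'   \code{log_e_I}, \code{log_e_T} and attribute \code{regime}. In the
#'   linear regime with nonpositive fitness the log columns are \code{NaN}.
#' @examples
#' p <- builtin_scenarios()$fig1b
#' fitness(p, 1)  # linear: e_I = 0.9 + 0.1 * (-3.2) = 0.58, e_T = 1.14
#' @export
fitness <- function(params, i, regime = "auto") {
  regime <- resolve_regime(params, regime)
  er <- expected_revenues(params, i)
  xi <- params$xi
  out <- switch(regime,
    neutral = data.frame(i = er$i,
                         e_I = rep(1, nrow(er)), e_T = rep(1, nrow(er)),
                         log_e_I = rep(0, nrow(er)), log_e_T = rep(0, nrow(er))),
    linear = {
      e_I <- 1 - xi + xi * er$E_I
      e_T <- 1 - xi + xi * er$E_T
      data.frame(i = er$i, e_I = e_I, e_T = e_T,
                 log_e_I = suppressWarnings(log(e_I)),
                 log_e_T = suppressWarnings(log(e_T)))
    },
    exponential = data.frame(i = er$i,
                             e_I = exp(xi * er$E_I), e_T = exp(xi * er$E_T),
                             log_e_I = xi * er$E_I, log_e_T = xi * er$E_T))
  attr(out, "regime") <- regime
  out
}

#' Log fitness ratio log(e_T / e_I)
#'
#' The quantity whose cumulative sums drive the exact fixation formulas: the
#' product over states of \eqn{e_{nT}/e_{nI}} becomes a sum of these logs.
#' In the exponential regime it equals \eqn{\xi (E_{iT} - E_{iI})} exactly.
#'
#' @inheritParams fitness
#' @return Numeric vector, \eqn{\log e_{iT} - \log e_{iI}} per state.
#' @export
fitness_ratio_log <- function(params, i, regime = "auto") {
  regime <- resolve_regime(params, regime)
  if (regime == "exponential") {
    er <- expected_revenues(params, i)
    return(params$xi * (er$E_T - er$E_I))
  }
  f <- fitness(params, i, regime)
  f$log_e_T - f$log_e_I
}

# Chain computations need strictly positive fitness at every interior state.
check_positive_fitness <- function(params, regime) {
  regime <- resolve_regime(params, regime)
  if (regime %in% c("neutral", "exponential")) return(regime)
  f <- fitness(params, seq_len(params$N - 1L), regime)
  if (any(f$e_I <= 0) || any(f$e_T <= 0))
    stop(errorCondition(
      paste("nonpositive-fitness: the linear map 1 - xi + xi*E is <= 0 at",
            "some interior state; Moran chain probabilities are undefined.",
            "Use the exponential regime for this parameter set."),
      class = c("morangame_nonpositive_fitness", "error")))
  regime
}
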