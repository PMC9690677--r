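#' Invasion diagnostics: fitness differences and ratios at the boundaries
#'
#' The edge states decide invasion. At one innovator the fitness difference
#' is
#' \deqn{h_1 = \eta_2 R_I + \lambda R_T + C_{pl} - C_{ph} - R_T,}
#' and at \code{N - 1} innovators
#' \deqn{h_{N-1} = \frac{N-2}{N-1}\eta_1 R_I + \frac{1}{N-1}\eta_2 R_I
#'   + \lambda R_T + C_{pl} - C_{ph} - R_T.}
#' These are the \eqn{\xi = 1} (expected-revenue) differences
#' \eqn{E_{iI} - E_{iT}}. Under the exponential map the corresponding
#' ratios are \eqn{f = \exp(\xi h)}; since \eqn{\exp} is monotone,
#' \eqn{\mathrm{sign}(f - 1) = \mathrm{sign}(h)} for any \eqn{\xi > 0},
#' so both analyses classify identically. \code{g = f - 1} is also
#' returned (the quantity conventionally plotted).
#'
#' @param params A \code{\link{game_params}} object.
#' @param xi Selection intensity used for the ratios \code{f}; defaults to
#'   \code{params$xi}.
#' @return A list with \code{h1}, \code{hN1}, \code{f1}, \code{fN1},
#'   \code{g1}, \code{gN1}.
#' @examples
#' p <- builtin_scenarios()$fig3a  # eta1 = 0.7, eta2 = 0.3, lam = 0.2
#' invasion_diffs(update_params(p, N = 5))$h1  # -12.1
#' @export
invasion_diffs <- function(params, xi = params$xi) {
  stopifnot(inherits(params, "game_params"))
  validate_game_params(params)
  base <- params$lam * params$RT + params$Cpl - params$Cph - params$RT
  h1 <- params$eta2 * params$RI + base
  N <- params$N
  hN1 <- ((N - 2) * params$eta1 * params$RI + params$eta2 * params$RI) /
    (N - 1) + base
  list(h1 = h1, hN1 = hN1,
       f1 = exp(xi * h1), fN1 = exp(xi * hN1),
       g1 = expm1(xi * h1), gN1 = expm1(xi * hN1))
}

classify_from_signs <- function(s1, sN1, evidence, basis) {
  label <- if (s1 == 0 && sN1 == 0) "tie"
  else if (s1 > 0 && sN1 > 0) "I_replaces_T"
  else if (s1 < 0 && sN1 < 0) "T_replaces_I"
  else if (s1 > 0 && sN1 < 0) "coexist"
  else if (s1 < 0 && sN1 > 0) "bistable"
  else if (sN1 > 0 || s1 > 0) "I_replaces_T"   # one strict +, one exact 0
  else "T_replaces_I"                          # one strict -, one exact 0
  new_classification(label, evidence, basis)
}

#' Classification under the dominance of expected revenue (xi = 1)
#'
#' Invasion logic from the signs of \code{h1} and \code{hN1}: both
#' positive, the R&D innovation strategy replaces the non-R&D strategy and
#' becomes the evolutionary stable solution; both negative, the reverse;
#' \code{h1 > 0 > hN1}, neither pure state resists the other's rare mutant
#' so the two strategies coexist (mixed outcome); \code{h1 < 0 < hN1},
#' each pure state resists invasion (bistable; a sign pattern the
#' expected-revenue case list does not discuss but which occurs for
#' realistic parameters, e.g. the baseline with \code{lam = 0.3}).
#'
#' @param params A \code{\link{game_params}} object.
#' @return A \code{regime_classification} with basis \code{"h_signs"}.
#' @examples
#' classify_strong(update_params(builtin_scenarios()$fig3a, N = 5))
#' @export
classify_strong <- function(params) {
  d <- invasion_diffs(params)
  classify_from_signs(sign(d$h1), sign(d$hN1),
                      list(h1 = d$h1, hN1 = d$hN1), "h_signs")
}

#' Classification under the dominance of super expected revenue (xi > 1)
#'
#' Uses the exponential-fitness ratios \code{f1}, \code{fN1} against 1.
#' Because \eqn{\mathrm{sign}(f - 1) = \mathrm{sign}(h)}, the label always
#' coincides with \code{\link{classify_strong}} and the group-size
#' threshold is unchanged: amplifying revenues exponentially changes how
#' fast selection acts, not which strategy it favours.
#'
#' @param params A \code{\link{game_params}} object; intended for
#'   \code{xi > 1} but any \code{xi > 0} is accepted.
#' @return A \code{regime_classification} with basis \code{"f_signs"}.
#' @examples
#' classify_super(update_params(builtin_scenarios()$fig4, N = 50))
#' @export
classify_super <- function(params) {
  if (params$xi <= 0)
    stop(errorCondition(
      "invalid-parameter: super-expected-revenue analysis needs xi > 0",
      class = c("morangame_invalid_parameter", "error")))
  d <- invasion_diffs(params)
  classify_from_signs(sign(d$g1), sign(d$gN1),
                      list(f1 = d$f1, fN1 = d$fN1), "f_signs")
}

#' Group-size threshold N0 for the strategy switch
#'
#' Treating \code{N} as real, \code{hN1} crosses zero at
#' \deqn{N_0 = \frac{2\eta_1 R_I - \eta_2 R_I + \lambda R_T - R_T - C_{ph} + C_{pl}}
#'              {\eta_1 R_I + \lambda R_T - R_T - C_{ph} + C_{pl}}.}
#' When the applicability sign
#' \eqn{\eta_2 R_I + \lambda R_T - R_T - (C_{ph} - C_{pl})} is positive,
#' \code{hN1} increases with \code{N}: below \code{N0} the strategies
#' coexist, above it the R&D innovation strategy is the evolutionary
#' stable solution. When negative, \code{hN1} decreases and the non-R&D
#' strategy takes over at large \code{N}. The same threshold governs the
#' super-expected-revenue regime (\code{N1 = N0}).
#'
#' @param params A \code{\link{game_params}} object.
#' @return A list with \code{N0} (real), \code{applicability} (the sign
#'   quantity above, which equals \code{h1}), and a human-readable
#'   \code{interpretation}.
#' @examples
#' threshold_N0(builtin_scenarios()$fig3a)  # N0 = 15.9 / 1.9
#' @export
threshold_N0 <- function(params) {
  stopifnot(inherits(params, "game_params"))
  validate_game_params(params)
  e1RI <- params$eta1 * params$RI
  e2RI <- params$eta2 * params$RI
  base <- params$lam * params$RT - params$RT - params$Cph + params$Cpl
  den <- e1RI + base
  if (den == 0)
    stop(errorCondition(
      "degenerate-threshold: hN1 does not depend on N (denominator is 0)",
      class = c("morangame_degenerate_threshold", "error")))
  N0 <- (2 * e1RI - e2RI + base) / den
  applicability <- e2RI + base
  interpretation <- if (applicability > 0) {
    "hN1 increases with N: coexistence below N0, R&D innovation ESS above N0"
  } else if (applicability < 0) {
    "hN1 decreases with N: non-R&D innovation becomes the ESS at large N"
  } else {
    "boundary case: h1 = 0 exactly"
  }
  list(N0 = N0, applicability = applicability, interpretation = interpretation)
}
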