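#' First-order weak-selection coefficients
#'
#' Under weak selection (\eqn{\xi \to 0}, strategy choice dominated by
#' external factors) the exact fixation probabilities expand as
#' \deqn{\rho_I \approx \frac{1}{N} + \frac{\xi}{6N}(\alpha + N\beta), \qquad
#'   \rho_T \approx \frac{1}{N} + \frac{\xi}{6N}(\gamma + N\delta),}
#' with coefficients (currency units)
#' \deqn{\alpha = (-2\eta_1 - \eta_2)R_I + 3(1-\lambda)R_T + 3C_{ph} - 3C_{pl},}
#' \deqn{\beta = (\eta_1 + 2\eta_2)R_I - 3(1-\lambda)R_T - 3C_{ph} + 3C_{pl},}
#' \deqn{\gamma = (4\eta_1 - \eta_2)R_I - 3(1-\lambda)R_T - 3C_{ph} + 3C_{pl},}
#' and \eqn{\delta = \alpha} (the two formulas coincide).
#'
#' @param params A \code{\link{game_params}} object.
#' @return A named list with \code{alpha}, \code{beta}, \code{gamma},
#'   \code{delta}.
#' @examples
#' weak_coeffs(builtin_scenarios()$fig1b)
#' # alpha = -8.8, beta = -5.2, gamma = 36.8, delta = -8.8
#' @export
weak_coeffs <- function(params) {
  stopifnot(inherits(params, "game_params"))
  validate_game_params(params)
  with(unclass(params), {
    alpha <- (-2 * eta1 - eta2) * RI + 3 * (1 - lam) * RT + 3 * Cph - 3 * Cpl
    beta <- (eta1 + 2 * eta2) * RI - 3 * (1 - lam) * RT - 3 * Cph + 3 * Cpl
    gamma <- (4 * eta1 - eta2) * RI - 3 * (1 - lam) * RT - 3 * Cph + 3 * Cpl
    list(alpha = alpha, beta = beta, gamma = gamma, delta = alpha)
  })
}

#' Weak-selection (Taylor) approximation of the fixation probabilities
#'
#' First-order expansion around the neutral value \code{1/N}; accurate to
#' \eqn{O(\xi^2)}. No cutoff on \code{xi} is enforced: the caller decides
#' whether the expansion is appropriate.
#'
#' @param params A \code{\link{game_params}} object.
#' @return A named list with \code{rho_I}, \code{rho_T}.
#' @examples
#' p <- update_params(builtin_scenarios()$fig1b, N = 4)
#' rho_weak_approx(p)
#' @export
rho_weak_approx <- function(params) {
  co <- weak_coeffs(params)
  N <- params$N
  xi <- params$xi
  list(rho_I = 1 / N + xi * (co$alpha + N * co$beta) / (6 * N),
       rho_T = 1 / N + xi * (co$gamma + N * co$delta) / (6 * N))
}

new_classification <- function(label, evidence, basis) {
  structure(list(label = label, evidence = evidence, basis = basis),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("Classification: %s (basis: %s)\n", x$label, x$basis))
  ev <- unlist(x$evidence)
  cat(paste0("  ", names(ev), " = ", signif(ev, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Classify strategies against the neutral 1/N benchmark
#'
#' A strategy is favoured by selection when its fixation probability from a
#' single mutant exceeds the neutral value \code{1/N}. Compares
#' \code{rho_I} and \code{rho_T} (exact by default; the first-order
#' approximation on request) against \code{1/N} and labels the outcome.
#'
#' @inheritParams fitness
#' @param approx Use the Taylor approximation instead of the exact formulas.
#' @param tol Tie tolerance on \code{|rho - 1/N|}.
#' @return A \code{regime_classification} with label one of
#'   \code{"I_replaces_T"}, \code{"T_replaces_I"},
#'   \code{"mutual_invasion"}, \code{"neither_roots"}, \code{"tie"}, the
#'   signed evidence, and basis \code{"rho_vs_1overN"}.
#' @examples
#' classify_weak(update_params(builtin_scenarios()$fig1b, N = 4))
#' @export
classify_weak <- function(params, regime = "auto", approx = FALSE,
                          tol = 1e-12) {
  if (approx) {
    r <- rho_weak_approx(params)
  } else {
    fx <- fixation_recursive(params, regime)
    r <- list(rho_I = fx$rho_I, rho_T = fx$rho_T)
  }
  N <- params$N
  dI <- r$rho_I - 1 / N
  dT <- r$rho_T - 1 / N
  sI <- if (abs(dI) <= tol) 0 else sign(dI)
  sT <- if (abs(dT) <= tol) 0 else sign(dT)
  label <- if (sI == 0 && sT == 0) "tie"
  else if (sI > 0 && sT <= 0) "I_replaces_T"
  else if (sT > 0 && sI <= 0) "T_replaces_I"
  else if (sI > 0 && sT > 0) "mutual_invasion"
  else "neither_roots"
  new_classification(label,
                    list(rho_I = r$rho_I, rho_T = r$rho_T, one_over_N = 1 / N),
                    "rho_vs_1overN")
}

#' Weak-selection invasion condition for the R&D strategy
#'
#' Evaluates the margin
#' \eqn{\eta_2 R_I - C_{ph} - (R_T - \lambda R_T - C_{pl})}: a lone
#' innovator's payoff minus a non-innovator's. When this is positive and
#' \eqn{\eta_1 > \eta_2} (cooperation helps), weak selection favours the
#' R&D innovation strategy replacing the non-R&D strategy at every group
#' size.
#'
#' @param params A \code{\link{game_params}} object.
#' @return A list with \code{margin}, \code{holds} (margin > 0),
#'   \code{eta1_gt_eta2}.
#' @examples
#' proposition1_condition(builtin_scenarios()$fig1b)  # margin = -6.4
#' @export
proposition1_condition <- function(params) {
  stopifnot(inherits(params, "game_params"))
  margin <- params$eta2 * params$RI - params$Cph -
    (params$RT - params$lam * params$RT - params$Cpl)
  list(margin = margin, holds = margin > 0,
       eta1_gt_eta2 = params$eta1 > params$eta2)
}
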