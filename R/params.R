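#' Model parameters for the R&D innovation Moran game
#'
#' Bundles all constants of the finite-population evolutionary game between
#' the R&D innovation strategy (I) and the non-R&D innovation strategy (T):
#' production costs, revenues, R&D success probabilities, the tax-incentive
#' rate, the group size and the selection intensity.
#'
#' @param Cpl Production cost of the non-R&D (traditional) strategy, currency units.
#' @param Cph Production cost of the R&D innovation strategy, currency units.
#' @param RT Revenue of the non-R&D strategy, currency units.
#' @param RI Revenue of the R&D innovation strategy (when R&D succeeds), currency units.
#' @param eta1 R&D success probability when both partners innovate (industry
#'   cooperation), in \code{[0, 1]}.
#' @param eta2 R&D success probability when only one partner innovates, in \code{[0, 1]}.
#' @param lam Tax-incentive rate \eqn{\lambda}: innovators are exempted the
#'   fraction \eqn{\lambda R_T} of the traditional revenue, which
#'   non-innovators pay. In \code{[0, 1]}.
#' @param N Group size: number of pharmaceutical enterprises, integer \code{>= 2}.
#' @param xi Selection intensity \eqn{\xi \ge 0}. \code{xi = 0} is the exact
#'   neutral limit; \code{0 < xi <= 1} is the linear (expected-revenue)
#'   regime, \code{xi > 1} the exponential (super-expected-revenue) regime.
#'
#' @return An object of class \code{game_params}: a named list of the nine
#'   parameters, validated against the model invariants.
#' @examples
#' p <- game_params(Cpl = 13, Cph = 18, RT = 22, RI = 35,
#'                  eta1 = 0.8, eta2 = 0.4, lam = 0.3, N = 6, xi = 0.1)
#' p
#' @export
game_params <- function(Cpl, Cph, RT, RI, eta1, eta2, lam, N, xi) {
  p <- list(Cpl = as.numeric(Cpl), Cph = as.numeric(Cph),
            RT = as.numeric(RT), RI = as.numeric(RI),
            eta1 = as.numeric(eta1), eta2 = as.numeric(eta2),
            lam = as.numeric(lam), N = as.integer(N), xi = as.numeric(xi))
  class(p) <- "game_params"
  validate_game_params(p)
  p
}

validate_game_params <- function(p) {
  stop_invalid <- function(msg) {
    stop(errorCondition(paste0("invalid-parameter: ", msg),
                        class = c("morangame_invalid_parameter", "error")))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("Cpl", "Cph", "RT", "RI", "eta1", "eta2", "lam", "xi"))
    if (!num1(p[[f]])) stop_invalid(paste0(f, " must be a single finite number"))
  if (p$eta1 < 0 || p$eta1 > 1) stop_invalid("eta1 must lie in [0, 1]")
  if (p$eta2 < 0 || p$eta2 > 1) stop_invalid("eta2 must lie in [0, 1]")
  if (p$lam < 0 || p$lam > 1) stop_invalid("lam must lie in [0, 1]")
  if (is.na(p$N) || p$N < 2L) stop_invalid("N must be an integer >= 2")
  if (p$xi < 0) stop_invalid("xi must be >= 0")
  invisible(p)
}

#' @export
print.game_params <- function(x, ...) {
  cat("Moran R&D game parameters\n")
  cat(sprintf("  costs     Cpl = %g (non-R&D), Cph = %g (R&D)\n", x$Cpl, x$Cph))
  cat(sprintf("  revenues  RT  = %g (non-R&D), RI  = %g (R&D)\n", x$RT, x$RI))
  cat(sprintf("  success   eta1 = %g (cooperating), eta2 = %g (alone)\n",
              x$eta1, x$eta2))
  cat(sprintf("  tax rate  lambda = %g   group size N = %d   selection xi = %g\n",
              x$lam, x$N, x$xi))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named fields replaced, revalidated.
#'
#' @param params A \code{\link{game_params}} object.
#' @param ... Named fields to replace (any of \code{Cpl, Cph, RT, RI, eta1,
#'   eta2, lam, N, xi}).
#' @return A new \code{game_params} object.
#' @examples
#' p <- builtin_scenarios()$fig1a
#' update_params(p, lam = 0.3, N = 10)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "game_params"))
  upd <- list(...)
  bad <- setdiff(names(upd), names(unclass(params)))
  if (length(bad))
    stop(errorCondition(
      paste0("invalid-parameter: unknown field(s): ", paste(bad, collapse = ", ")),
      class = c("morangame_invalid_parameter", "error")))
  p <- unclass(params)
  p[names(upd)] <- upd
  do.call(game_params, p)
}

#' Read game parameters from a YAML or JSON config file
#'
#' The file must contain the keys \code{Cpl, Cph, RT, RI, eta1, eta2, lam, N,
#' xi}, either at top level or under a \code{base:} block (the sweep-config
#' layout).
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{\link{game_params}} object.
#' @examples
#' cfg <- system.file("extdata", "baseline.yaml", package = "morangame")
#' read_game_params(cfg)
#' @export
read_game_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$base)) raw <- raw$base
  # a bare key `N` is a YAML-1.1 boolean; accept the mangled name too
  names(raw)[names(raw) == "FALSE"] <- "N"
  need <- c("Cpl", "Cph", "RT", "RI", "eta1", "eta2", "lam", "N", "xi")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop(errorCondition(
      paste0("invalid-parameter: config lacks key(s): ",
             paste(missing, collapse = ", ")),
      class = c("morangame_invalid_parameter", "error")))
  do.call(game_params, raw[need])
}
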