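#' Packaged simulation scenarios
#'
#' The baseline pharmaceutical-market scenario (non-R&D cost 13, revenue
#' 22; R&D cost 18, revenue 35) with the variable bindings used in each
#' panel of the simulation study:
#' \describe{
#'   \item{baseline}{costs/revenues only, neutral defaults elsewhere
#'     (\code{eta1 = 0.8}, \code{eta2 = 0.4}, \code{lam = 0.1},
#'     \code{N = 6}, \code{xi = 0.1}).}
#'   \item{fig1a / fig1b}{weak selection \code{xi = 0.1},
#'     \code{eta1 = 0.8}, \code{eta2 = 0.4}; low (\code{lam = 0.1}) vs
#'     high (\code{lam = 0.3}) tax incentive; sweeps over \code{N}.}
#'   \item{fig2}{\code{xi = 0.01}, \code{lam = 0.2}, \code{N = 50};
#'     sweeps over \code{(eta1, eta2)}.}
#'   \item{fig3a / fig3b}{expected-revenue dominance \code{xi = 1},
#'     \code{eta2 = 0.3} with \code{eta1 = 0.7} vs \code{eta1 = 0.5}.}
#'   \item{fig4}{super expected revenue \code{xi = 1.5},
#'     \code{eta1 = 0.7}, \code{eta2 = 0.3}, \code{lam = 0.2}.}
#' }
#'
#' @return A named list of \code{\link{game_params}} objects.
#' @examples
#' names(builtin_scenarios())
#' builtin_scenarios()$baseline
#' @export
builtin_scenarios <- function() {
  base <- function(...) game_params(Cpl = 13, Cph = 18, RT = 22, RI = 35, ...)
  list(
    baseline = base(eta1 = 0.8, eta2 = 0.4, lam = 0.1, N = 6, xi = 0.1),
    fig1a = base(eta1 = 0.8, eta2 = 0.4, lam = 0.1, N = 6, xi = 0.1),
    fig1b = base(eta1 = 0.8, eta2 = 0.4, lam = 0.3, N = 6, xi = 0.1),
    fig2 = base(eta1 = 0.8, eta2 = 0.4, lam = 0.2, N = 50, xi = 0.01),
    fig3a = base(eta1 = 0.7, eta2 = 0.3, lam = 0.2, N = 10, xi = 1),
    fig3b = base(eta1 = 0.5, eta2 = 0.3, lam = 0.2, N = 10, xi = 1),
    fig4 = base(eta1 = 0.7, eta2 = 0.3, lam = 0.2, N = 50, xi = 1.5)
  )
}

sweep_outputs_all <- c("rho_I", "rho_T", "N_rho_I", "N_rho_T",
                       "h1", "hN1", "g1", "gN1", "N0", "classification")

# evaluate the requested outputs at one parameter point; errors are caught
# and recorded so a sweep never silently drops a grid point
eval_point <- function(params, outputs, regime) {
  out <- stats::setNames(as.list(rep(NA, length(outputs))), outputs)
  out$error <- NA_character_
  tryCatch({
    if (any(c("rho_I", "rho_T", "N_rho_I", "N_rho_T") %in% outputs)) {
      fx <- fixation_recursive(params, regime)
      out$rho_I <- fx$rho_I
      out$rho_T <- fx$rho_T
      out$N_rho_I <- params$N * fx$rho_I
      out$N_rho_T <- params$N * fx$rho_T
    }
    if (any(c("h1", "hN1", "g1", "gN1") %in% outputs)) {
      d <- invasion_diffs(params)
      out[c("h1", "hN1", "g1", "gN1")] <- d[c("h1", "hN1", "g1", "gN1")]
    }
    if ("N0" %in% outputs) out$N0 <- threshold_N0(params)$N0
    if ("classification" %in% outputs)
      out$classification <- classify_strong(params)$label
  }, error = function(e) out$error <<- conditionMessage(e))
  out[c(outputs, "error")]
}

#' Evaluate model quantities over a parameter grid
#'
#' Runs the analytic modules over a one- or two-axis grid of parameter
#' values and returns a tidy table, one row per grid point. Failed points
#' (e.g. nonpositive linear fitness) carry their error message in the
#' \code{error} column and the run continues. Fully deterministic.
#'
#' @param base A \code{\link{game_params}} object: the values held fixed.
#' @param axis1,axis2 Lists \code{list(name = <field>, values = <vector>)};
#'   \code{axis2} may be \code{NULL} for a one-dimensional sweep.
#' @param outputs Character vector of requested quantities, a subset of
#'   \code{rho_I, rho_T, N_rho_I, N_rho_T, h1, hN1, g1, gN1, N0,
#'   classification}.
#' @param regime Selection regime passed to the fixation engine.
#' @return A data frame of class \code{sweep_result} with the axis
#'   columns, the requested outputs and an \code{error} column; regime and
#'   base parameters are kept as attributes.
#' @examples
#' sw <- run_sweep(builtin_scenarios()$fig1b,
#'                 axis1 = list(name = "N", values = 2:12),
#'                 outputs = c("N_rho_I", "N_rho_T"))
#' head(sw)
#' @export
run_sweep <- function(base, axis1, axis2 = NULL,
                      outputs = c("rho_I", "rho_T"), regime = "auto") {
  stopifnot(inherits(base, "game_params"))
  check_axis <- function(ax) {
    if (!is.list(ax) || is.null(ax$name) || is.null(ax$values) ||
        !ax$name %in% names(unclass(base)) || !length(ax$values) ||
        !all(is.finite(ax$values)))
      stop(errorCondition(
        "invalid-parameter: axis must be list(name = <param field>, values = <finite, nonempty>)",
        class = c("morangame_invalid_parameter", "error")))
    ax
  }
  axis1 <- check_axis(axis1)
  if (!is.null(axis2)) axis2 <- check_axis(axis2)
  bad <- setdiff(outputs, sweep_outputs_all)
  if (length(bad))
    stop(errorCondition(
      paste0("invalid-parameter: unknown output(s): ", paste(bad, collapse = ", ")),
      class = c("morangame_invalid_parameter", "error")))

  grid <- if (is.null(axis2)) {
    stats::setNames(data.frame(axis1$values), axis1$name)
  } else {
    stats::setNames(expand.grid(axis1$values, axis2$values,
                                KEEP.OUT.ATTRS = FALSE),
                    c(axis1$name, axis2$name))
  }
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    upd <- as.list(grid[r, , drop = FALSE])
    p <- do.call(update_params, c(list(base), upd))
    c(upd, eval_point(p, outputs, regime))
  })
  res <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  attr(res, "regime") <- regime
  attr(res, "base") <- base
  class(res) <- c("sweep_result", class(res))
  res
}

#' Write a sweep result to CSV
#'
#' Writes RFC-4180 CSV with a single comment header line carrying the
#' regime and package version, so the data rows are byte-identical across
#' reruns of the same spec.
#'
#' @param result A \code{sweep_result}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# morangame %s sweep, regime=%s, written %s",
                     as.character(utils::packageVersion("morangame")),
                     attr(result, "regime") %||% "auto", Sys.time()), con)
  utils::write.csv(as.data.frame(result), con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a sweep result
#'
#' Line plot of the requested quantities against the sweep axis, one curve
#' per value of the optional second axis, with a horizontal reference line
#' at \code{ref} (1 for \code{N_rho} curves, 0 for \code{h}/\code{g}
#' curves).
#'
#' @param result A \code{sweep_result} from \code{\link{run_sweep}}.
#' @param x Name of the axis column to put on the x axis.
#' @param outputs Which output columns to draw; default: all numeric
#'   outputs present.
#' @param ref Height of the horizontal reference line, or \code{NULL} for
#'   none.
#' @return A \code{ggplot} object.
#' @export
plot_sweep <- function(result, x, outputs = NULL, ref = NULL) {
  cols <- setdiff(names(result), c(x, "error"))
  if (is.null(outputs)) outputs <- cols[vapply(result[cols], is.numeric, TRUE)]
  missing <- setdiff(outputs, names(result))
  if (length(missing))
    stop(errorCondition(
      paste0("missing-column: not in sweep result: ",
             paste(missing, collapse = ", ")),
      class = c("morangame_missing_column", "error")))
  if (!nrow(result))
    stop(errorCondition("missing-column: empty sweep result",
                        class = c("morangame_missing_column", "error")))
  long <- do.call(rbind, lapply(outputs, function(o)
    data.frame(xval = result[[x]], quantity = o, value = result[[o]])))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = xval, y = value, colour = quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = x, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(ref))
    p <- p + ggplot2::geom_hline(yintercept = ref, linetype = "dashed")
  p
}
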