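#' Run the cost-effectiveness comparison
#'
#' Evaluates both strategies (FOLFOX-HAIC and TACE) on the given parameter
#' set and computes the incremental comparison: incremental cost,
#' incremental QALYs, ICER and net monetary benefit at the
#' willingness-to-pay threshold.
#'
#' @param ps an `hcc_params` parameter set, e.g. [baseline_parameters()].
#' @param wtp willingness-to-pay per QALY; defaults to the structural
#'   setting ($30,552/QALY, three times China's 2020 per-capita GDP).
#' @return object of class `hcc_cea` with per-strategy results
#'   (`$FOLFOX_HAIC`, `$TACE`) and the `$comparison` [icer()] object.
#' @examples
#' fit <- run_cea(baseline_parameters())
#' fit
#' summary(fit)
#' @export
run_cea <- function(ps, wtp = ps$structural$wtp_per_qaly) {
  validate_parameters(ps)
  res <- lapply(strategy_names(), function(s) evaluate_strategy(ps, s))
  names(res) <- strategy_names()
  cmp <- icer(ref = res$TACE, comp = res$FOLFOX_HAIC, wtp = wtp)
  structure(list(FOLFOX_HAIC = res$FOLFOX_HAIC, TACE = res$TACE,
                 comparison = cmp, params = ps),
            class = "hcc_cea")
}

#' Incremental cost-effectiveness ratio
#'
#' Incremental values are `comp - ref`. When the signs of the increments
#' differ one strategy dominates: `comp` is `dominant` when it is cheaper
#' and at least as effective, `dominated` when costlier and no more
#' effective. Cost-effectiveness is judged by net monetary benefit
#' \eqn{NMB = wtp \times \Delta QALY - \Delta Cost}, with NMB = 0 counted
#' as cost-effective.
#'
#' @param ref,comp `strategy_result` objects (see [evaluate_strategy()]),
#'   or lists with elements `cost` (having a `total`) and `qalys`.
#' @param wtp willingness-to-pay per QALY (USD).
#' @return object of class `icer_comparison`.
#' @export
icer <- function(ref, comp, wtp) {
  total <- function(x) unname(if (length(x$cost) > 1) x$cost[["total"]] else x$cost)
  d_cost <- total(comp) - total(ref)
  d_qaly <- comp$qalys - ref$qalys
  dominance <- NA_character_
  icer_val <- NA_real_
  if (abs(d_qaly) < 1e-12) {
    if (d_cost > 0) dominance <- "dominated"
    else if (d_cost < 0) dominance <- "dominant"
    else icer_val <- 0
  } else if (d_qaly > 0 && d_cost <= 0) {
    dominance <- "dominant"
  } else if (d_qaly < 0 && d_cost >= 0) {
    dominance <- "dominated"
  } else {
    icer_val <- d_cost / d_qaly
  }
  nmb <- wtp * d_qaly - d_cost
  structure(list(incremental_cost = d_cost, incremental_qalys = d_qaly,
                 icer = icer_val, dominance = dominance, wtp = wtp,
                 nmb = nmb, cost_effective = nmb >= 0),
            class = "icer_comparison")
}

#' @export
print.icer_comparison <- function(x, ...) {
  cat(sprintf("  incremental cost:  $%s\n", format(round(x$incremental_cost), big.mark = ",")))
  cat(sprintf("  incremental QALYs: %.3f\n", x$incremental_qalys))
  if (!is.na(x$dominance)) {
    cat(sprintf("  %s\n", x$dominance))
  } else {
    cat(sprintf("  ICER:              $%s/QALY\n", format(round(x$icer), big.mark = ",")))
  }
  cat(sprintf("  NMB at WTP $%s/QALY: $%s (%scost-effective)\n",
              format(x$wtp, big.mark = ","), format(round(x$nmb), big.mark = ","),
              if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' @export
print.hcc_cea <- function(x, ...) {
  cat("Cost-effectiveness of FOLFOX-HAIC versus TACE in large unresectable HCC\n\n")
  print(x$FOLFOX_HAIC)
  print(x$TACE)
  cat("\nIncremental (FOLFOX-HAIC vs TACE):\n")
  print(x$comparison)
  invisible(x)
}

#' @export
summary.hcc_cea <- function(object, ...) {
  strat <- rbind(FOLFOX_HAIC = c(object$FOLFOX_HAIC$cost[["total"]],
                                 object$FOLFOX_HAIC$qalys, object$FOLFOX_HAIC$lys),
                 TACE = c(object$TACE$cost[["total"]], object$TACE$qalys, object$TACE$lys))
  colnames(strat) <- c("cost", "qalys", "lys")
  breakdown <- rbind(FOLFOX_HAIC = object$FOLFOX_HAIC$cost,
                     TACE = object$TACE$cost)
  out <- list(strategies = strat, cost_breakdown = breakdown,
              comparison = object$comparison)
  class(out) <- "summary.hcc_cea"
  out
}

#' @export
print.summary.hcc_cea <- function(x, ...) {
  cat("Strategy totals (discounted):\n")
  print(round(x$strategies, 3))
  cat("\nCost breakdown (USD):\n")
  print(round(x$cost_breakdown, 2))
  cat("\nIncremental comparison:\n")
  print(x$comparison)
  invisible(x)
}

#' Plot a fitted comparison: state occupancy over time for both arms
#'
#' @param x an `hcc_cea` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hcc_cea <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (s in strategy_names()) {
    tr <- x[[s]]$trace
    graphics::matplot(tr$time_months, tr$occupancy, type = "l", lty = 1,
                      xlab = "time (months)", ylab = "state occupancy",
                      main = s, ...)
    graphics::legend("right", colnames(tr$occupancy), col = 1:4, lty = 1, bty = "n")
  }
  invisible(x)
}
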