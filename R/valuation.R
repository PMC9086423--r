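#' Discount factor
#'
#' \eqn{(1 + r)^{-t}} with `t` in years, evaluated at cycle start.
#' @param t_years time in years (vectorized), `>= 0`.
#' @param annual_rate annual discount rate, `> -1`.
#' @export
discount_factor <- function(t_years, annual_rate) {
  if (any(t_years < 0)) stop("discount_factor: t_years must be >= 0")
  if (annual_rate <= -1) stop("discount_factor: annual_rate must be > -1")
  (1 + annual_rate)^(-t_years)
}

# session calendar for a treatment course: start times (days, relative to
# course start) and weights (a fractional mean session count weights the
# final session, e.g. 3.6 sessions -> weights 1,1,1,0.6)
session_schedule <- function(n_sessions, interval_days) {
  j <- seq_len(ceiling(n_sessions))
  data.frame(t_days = (j - 1) * interval_days,
             weight = pmin(1, n_sessions - (j - 1)))
}

sum_uncertain <- function(lst) sum(vapply(lst, function(p) p$baseline, numeric(1)))

#' Accrue discounted costs over a cohort trace
#'
#' Cost components (all USD, discounted at the per-cycle rate):
#' \describe{
#'   \item{first_line}{per-session drug/procedure costs on the treatment
#'     calendar, weighted by PFD occupancy at each session time.}
#'   \item{hospitalization}{per-cycle hospitalization during first-line
#'     treatment cycles, weighted by PFD occupancy (a fractional final
#'     treatment cycle is weighted accordingly).}
#'   \item{hepatectomy}{one-off surgery cost for RFD entrants.}
#'   \item{bsc}{per-cycle best-supportive-care cost for the BSC share of PD
#'     occupancy, until death.}
#'   \item{crossover}{the other arm's treatment course for the crossover
#'     share of each PD entry cohort, sessions discounted at their own
#'     calendar times.}
#'   \item{ae}{one-off adverse-event management at model entry:
#'     sum of incidence x unit cost over grade >= 3 events.}
#' }
#'
#' @param trace a `cohort_trace` from [run_trace()].
#' @param ps the `hcc_params` parameter set.
#' @param strategy strategy name; defaults to the trace's.
#' @return named numeric vector of components plus `total`.
#' @export
accrue_costs <- function(trace, ps, strategy = trace$strategy) {
  sp <- ps$strategies[[strategy]]
  st <- ps$structural
  r <- ps$discount_rate_annual$baseline
  cyc_d <- trace$cycle_days
  n_cyc <- length(trace$cycle) - 1L
  disc <- discount_factor(trace$time_years, r)
  hcc <- isTRUE(st$half_cycle_correction)

  pfd <- trace$occupancy[, "PFD"]
  pd <- trace$occupancy[, "PD"]

  # (a) first-line sessions on their calendar schedule
  sched <- session_schedule(sp$n_sessions, sp$session_interval_days)
  sess_cost <- sum_uncertain(sp$per_session_costs)
  k_sess <- pmin(floor(sched$t_days / cyc_d), n_cyc) + 1L
  first_line <- sum(sched$weight * sess_cost * pfd[k_sess] *
                    discount_factor(sched$t_days / DAYS_PER_YEAR, r))

  # hospitalization during first-line treatment cycles, for strategies whose
  # administration requires admission (HAIC 24-h infusions; the TACE
  # procedure cost is taken as admission-inclusive)
  hosp <- 0
  if (isTRUE(sp$hospitalize_during_treatment)) {
    t_hep_days <- sp$n_sessions * sp$session_interval_days
    k_tx <- which(trace$time_years[1:n_cyc] * DAYS_PER_YEAR < t_hep_days)
    w_tx <- pmin(1, (t_hep_days - trace$time_years[k_tx] * DAYS_PER_YEAR) / cyc_d)
    hosp <- ps$shared_costs$hospitalization_per_cycle$baseline *
      sum(w_tx * pfd[k_tx] * disc[k_tx])
  }

  # (b) hepatectomy one-off at RFD entry
  hep <- ps$shared_costs$hepatectomy$baseline *
    sum(trace$entrants[, "RFD"] * disc)

  # (c) progressed disease: BSC share per cycle + crossover course at entry
  mix <- vapply(sp$subsequent_mix, function(p) p$baseline, numeric(1))
  mix <- mix / sum(mix)
  pd_w <- state_cycle_weights(pd, hcc)
  bsc <- ps$shared_costs$bsc_per_cycle$baseline * mix[["BSC"]] *
    sum(pd_w * disc[1:n_cyc])

  other <- setdiff(strategy_names(), strategy)
  so <- ps$strategies[[other]]
  xsched <- session_schedule(so$n_sessions, so$session_interval_days)
  course_pv <- sum_uncertain(so$per_session_costs) *
    sum(xsched$weight * discount_factor(xsched$t_days / DAYS_PER_YEAR, r))
  crossover <- mix[["crossover"]] * course_pv * sum(trace$entrants[, "PD"] * disc)

  # (d) adverse events: one-off at model entry
  ae <- ae_entry_cost(ps, strategy)

  out <- c(first_line = first_line, hospitalization = hosp, hepatectomy = hep,
           bsc = bsc, crossover = crossover, ae = ae)
  c(out, total = sum(out))
}

ae_entry_cost <- function(ps, strategy) {
  inc <- ps$strategies[[strategy]]$ae_incidence
  costs <- ps$ae_costs
  inc$elevated_alt$baseline * costs$elevated_alt_ast$baseline +
    inc$elevated_ast$baseline * costs$elevated_alt_ast$baseline +
    inc$vomiting$baseline * costs$vomiting$baseline
}

ae_qaly_decrement <- function(ps, strategy, cycle_years) {
  inc <- ps$strategies[[strategy]]$ae_incidence
  dis <- ps$ae_disutilities
  (inc$elevated_alt$baseline * dis$elevated_alt_ast$baseline +
   inc$elevated_ast$baseline * dis$elevated_alt_ast$baseline +
   inc$vomiting$baseline * dis$vomiting$baseline) * cycle_years
}

#' Accrue discounted QALYs over a cohort trace
#'
#' Per cycle, utility 0.76 for PFD and RFD occupancy and 0.68 for PD
#' (baseline values; taken from the parameter set), times cycle length in
#' years, discounted; minus a one-off adverse-event disutility at entry
#' (incidence x disutility x one cycle's duration). Floored at zero.
#'
#' @inheritParams accrue_costs
#' @return discounted QALYs (scalar).
#' @export
accrue_qalys <- function(trace, ps, strategy = trace$strategy) {
  r <- ps$discount_rate_annual$baseline
  hcc <- isTRUE(ps$structural$half_cycle_correction)
  cyc_y <- trace$cycle_days / DAYS_PER_YEAR
  n_cyc <- length(trace$cycle) - 1L
  disc <- discount_factor(trace$time_years[1:n_cyc], r)
  u <- ps$utilities
  uw <- u$PFD$baseline * state_cycle_weights(trace$occupancy[, "PFD"], hcc) +
        u$RFD$baseline * state_cycle_weights(trace$occupancy[, "RFD"], hcc) +
        u$PD$baseline * state_cycle_weights(trace$occupancy[, "PD"], hcc)
  max(sum(uw * cyc_y * disc) - ae_qaly_decrement(ps, strategy, cyc_y), 0)
}

#' Evaluate one strategy: trace, costs, QALYs, life-years
#'
#' @param ps an `hcc_params` parameter set.
#' @param strategy strategy name.
#' @param trace optionally a precomputed `cohort_trace`.
#' @return object of class `strategy_result` with fields `strategy`,
#'   `cost` (component breakdown), `qalys`, `lys`, `trace`.
#' @export
evaluate_strategy <- function(ps, strategy = strategy_names(), trace = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(trace)) trace <- run_trace(ps, strategy)
  costs <- accrue_costs(trace, ps, strategy)
  structure(list(strategy = strategy, cost = costs,
                 qalys = accrue_qalys(trace, ps, strategy),
                 lys = life_years(trace, ps$discount_rate_annual$baseline,
                                  isTRUE(ps$structural$half_cycle_correction)),
                 trace = trace),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: cost $%s, %.3f QALYs, %.3f LYs\n", x$strategy,
              format(round(x$cost[["total"]]), big.mark = ","), x$qalys, x$lys))
  invisible(x)
}
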