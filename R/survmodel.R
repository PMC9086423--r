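#' Parametric survival model
#'
#' Constructs a parametric survival curve used for overall-survival (OS) and
#' progression-free-survival (PFS) extrapolation. Two families are supported:
#' \describe{
#'   \item{log_logistic}{\eqn{S(t) = 1 / (1 + \theta t^\kappa)} with
#'     \eqn{\theta > 0}, \eqn{\kappa > 0}.}
#'   \item{lognormal}{\eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)} with
#'     \eqn{\sigma > 0}.}
#' }
#' Time is measured in months (1 month = 30.4375 days).
#'
#' @param family `"log_logistic"` or `"lognormal"`.
#' @param params named numeric vector: `c(theta=, kappa=)` for the
#'   log-logistic family, `c(mu=, sigma=)` for the lognormal family.
#' @return An object of class `surv_model`.
#' @examples
#' os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
#' survival_at(os, c(0, 6, 12, 24))
#' median(os)  # (1/theta)^(1/kappa) months
#' @export
surv_model <- function(family = c("log_logistic", "lognormal"), params) {
  family <- match.arg(family)
  params <- unlist(params)
  need <- switch(family, log_logistic = c("theta", "kappa"), lognormal = c("mu", "sigma"))
  if (!all(need %in% names(params)))
    stop("surv_model(", family, ") requires parameters ", paste(need, collapse = ", "))
  params <- params[need]
  if (family == "log_logistic" && any(params <= 0))
    stop("log-logistic parameters theta and kappa must be positive")
  if (family == "lognormal" && params[["sigma"]] <= 0)
    stop("lognormal sigma must be positive")
  structure(list(family = family, params = params, time_unit = "months"),
            class = "surv_model")
}

#' @export
print.surv_model <- function(x, ...) {
  cat(sprintf("Parametric survival model (%s), time in %s\n", x$family, x$time_unit))
  print(x$params)
  cat(sprintf("median: %.4f months\n", median(x)))
  invisible(x)
}

#' Survival probability at time t
#'
#' @param model a [surv_model].
#' @param t time in months, vectorized, must be non-negative.
#' @param hr optional hazard ratio applied under proportional hazards,
#'   i.e. the returned value is \eqn{S(t)^{hr}}.
#' @return survival probabilities in `[0, 1]`.
#' @export
survival_at <- function(model, t, hr = 1) {
  stopifnot(inherits(model, "surv_model"))
  if (any(t < 0)) stop("survival_at: t must be >= 0")
  if (hr <= 0) stop("survival_at: hr must be > 0")
  p <- model$params
  s <- switch(model$family,
    log_logistic = 1 / (1 + p[["theta"]] * t^p[["kappa"]]),
    lognormal = ifelse(t == 0, 1, stats::pnorm(log(pmax(t, .Machine$double.xmin)),
                                               mean = p[["mu"]], sd = p[["sigma"]],
                                               lower.tail = FALSE)))
  unname(s^hr)
}

#' Median survival time (months)
#'
#' Closed forms: log-logistic \eqn{(1/\theta)^{1/\kappa}}; lognormal
#' \eqn{e^\mu}.
#' @param x a [surv_model].
#' @param na.rm ignored.
#' @param ... ignored.
#' @export
median.surv_model <- function(x, na.rm = FALSE, ...) {
  p <- x$params
  switch(x$family,
    log_logistic = (1 / p[["theta"]])^(1 / p[["kappa"]]),
    lognormal = exp(p[["mu"]]))
}

#' Apply a hazard ratio to a survival function
#'
#' Under proportional hazards a hazard ratio `hr` scales the cumulative
#' hazard, so the adjusted survival function is \eqn{S(t)^{hr}}.
#'
#' @param S a function of time returning survival probabilities.
#' @param hr hazard ratio, must be positive.
#' @return a new survival function of time.
#' @export
apply_hr <- function(S, hr) {
  stopifnot(is.function(S))
  if (!is.numeric(hr) || length(hr) != 1L || hr <= 0) stop("apply_hr: hr must be a positive scalar")
  force(S); force(hr)
  function(t) S(t)^hr
}

#' Conditional per-cycle event probability
#'
#' Probability that the event occurs in `(t_start, t_end]` given it has not
#' occurred by `t_start`: \eqn{1 - S(t_{end})/S(t_{start})}.
#'
#' @param S survival function of time (months).
#' @param t_start,t_end cycle boundaries in months, `0 <= t_start < t_end`.
#' @export
cycle_event_prob <- function(S, t_start, t_end) {
  if (any(t_start < 0) || any(t_end <= t_start)) stop("cycle_event_prob: need 0 <= t_start < t_end")
  s0 <- S(t_start)
  s1 <- S(t_end)
  ifelse(s0 <= 0, 1, pmin(pmax(1 - s1 / s0, 0), 1))
}

#' Convert an annual probability to a per-cycle probability
#'
#' Assumes a constant hazard within the year:
#' \eqn{p_{cycle} = 1 - (1 - p_{annual})^{d/365.25}} for a cycle of `d` days.
#'
#' @param p_annual annual probability in `[0, 1]`; 1 maps to 1.
#' @param cycle_days cycle length in days.
#' @export
annual_to_cycle_prob <- function(p_annual, cycle_days) {
  if (any(p_annual < 0 | p_annual > 1)) stop("annual_to_cycle_prob: p_annual must be in [0, 1]")
  ifelse(p_annual >= 1, 1, 1 - (1 - p_annual)^(cycle_days / 365.25))
}

# days per month used throughout (so one 21-day cycle = 0.6899 months)
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25
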