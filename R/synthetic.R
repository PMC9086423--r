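#' Simulate individual-patient survival data from a parametric model
#'
#' Draws event times by inverse-transform sampling from
#' \eqn{S(t)^{hr}} (the model's survival function under a proportional
#' hazard ratio) and applies administrative censoring at `cutoff` months.
#' Closed-form inverses: log-logistic
#' \eqn{t = ((u^{-1/hr} - 1)/\theta)^{1/\kappa}}; lognormal
#' \eqn{t = \exp(\mu + \sigma \Phi^{-1}(1 - u^{1/hr}))}, `u` uniform.
#'
#' @param model a [surv_model] (the generating distribution).
#' @param hr hazard ratio applied to the curve (1 for the reference arm).
#' @param n number of patients.
#' @param cutoff administrative censoring time in months (`Inf` for none).
#' @param seed optional integer seed.
#' @param arm,endpoint labels recorded on each row.
#' @return data.frame of class `pseudo_ipd` with columns `time` (months),
#'   `event` (1 event, 0 censored), `arm`, `endpoint`.
#' @export
simulate_ipd <- function(model, hr = 1, n, cutoff = 24, seed = NULL,
                         arm = "TACE", endpoint = "OS") {
  stopifnot(inherits(model, "surv_model"), n >= 1, cutoff > 0, hr > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  p <- model$params
  t_ev <- switch(model$family,
    log_logistic = ((u^(-1 / hr) - 1) / p[["theta"]])^(1 / p[["kappa"]]),
    lognormal = exp(p[["mu"]] + p[["sigma"]] * stats::qnorm(1 - u^(1 / hr))))
  event <- as.integer(t_ev <= cutoff)
  structure(data.frame(time = pmin(t_ev, cutoff), event = event,
                       arm = arm, endpoint = endpoint,
                       stringsAsFactors = FALSE),
            class = c("pseudo_ipd", "data.frame"))
}

loglik_llogis <- function(par, time, event) {
  theta <- exp(par[1]); kappa <- exp(par[2])
  lS <- -log1p(theta * time^kappa)
  lf <- log(theta) + log(kappa) + (kappa - 1) * log(time) + 2 * lS
  sum(event * lf + (1 - event) * lS)
}

loglik_lnorm <- function(par, time, event) {
  mu <- par[1]; sigma <- exp(par[2])
  lS <- stats::pnorm(log(time), mu, sigma, lower.tail = FALSE, log.p = TRUE)
  lf <- stats::dlnorm(time, mu, sigma, log = TRUE)
  sum(event * lf + (1 - event) * lS)
}

#' Fit a parametric survival model to right-censored data
#'
#' Maximum-likelihood estimation of a log-logistic
#' (\eqn{S(t) = 1/(1 + \theta t^\kappa)}) or lognormal model on
#' right-censored survival times, optimized on log-scale parameters with
#' standard errors from the observed information (delta method back to the
#' natural scale).
#'
#' @param ipd data.frame with columns `time` (> 0, months) and `event`
#'   (1 event, 0 censored), e.g. from [simulate_ipd()].
#' @param family `"log_logistic"` or `"lognormal"`.
#' @return object of class `parsurv_fit`: the fitted [surv_model]
#'   (`$model`), `$coefficients`, `$se`, `$vcov` (log/natural scale per
#'   family), `$loglik`, `$n`, `$n_events`.
#' @export
fit_parametric <- function(ipd, family = c("log_logistic", "lognormal")) {
  family <- match.arg(family)
  stopifnot(all(c("time", "event") %in% names(ipd)))
  time <- ipd$time
  event <- ipd$event
  if (any(time <= 0)) stop("fit_parametric: times must be positive")
  if (sum(event) < 10) stop("fit_parametric: need at least 10 events")
  med <- stats::median(time)
  if (family == "log_logistic") {
    ll <- function(par) -loglik_llogis(par, time, event)
    start <- c(ltheta = -log(med), lkappa = 0)   # theta ~ med^-1 at kappa = 1
  } else {
    ll <- function(par) -loglik_lnorm(par, time, event)
    start <- c(mu = mean(log(time)), lsigma = log(stats::sd(log(time))))
  }
  opt <- stats::optim(start, ll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("fit_parametric: optimizer failed to converge (code ", opt$convergence,
         "); ", opt$message %||% "")
  vc <- tryCatch(solve(opt$hessian), error = function(e)
    stop("fit_parametric: observed information is singular", call. = FALSE))
  if (family == "log_logistic") {
    est <- exp(opt$par)                       # (theta, kappa)
    se <- est * sqrt(diag(vc))                # delta method from log scale
    names(est) <- names(se) <- c("theta", "kappa")
    model <- surv_model("log_logistic", est)
  } else {
    est <- c(mu = unname(opt$par[1]), sigma = exp(unname(opt$par[2])))
    se <- c(mu = sqrt(vc[1, 1]), sigma = est[["sigma"]] * sqrt(vc[2, 2]))
    model <- surv_model("lognormal", est)
  }
  structure(list(model = model, coefficients = est, se = se, vcov = vc,
                 loglik = -opt$value, n = length(time), n_events = sum(event),
                 family = family),
            class = "parsurv_fit")
}

#' @export
print.parsurv_fit <- function(x, ...) {
  cat(sprintf("Parametric survival fit (%s): n = %d, events = %d, logLik = %.2f\n",
              x$family, x$n, x$n_events, x$loglik))
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' @export
coef.parsurv_fit <- function(object, ...) object$coefficients

#' @export
logLik.parsurv_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' Predicted survival probabilities from a fitted model
#' @param object a `parsurv_fit`.
#' @param times times in months.
#' @param ... unused.
#' @export
predict.parsurv_fit <- function(object, times, ...) {
  survival_at(object$model, times)
}

#' Simulate new data from a fitted parametric survival model
#' @param object a `parsurv_fit`.
#' @param nsim number of records.
#' @param seed optional integer seed.
#' @param cutoff administrative censoring time (months).
#' @param ... unused.
#' @export
simulate.parsurv_fit <- function(object, nsim = object$n, seed = NULL,
                                 cutoff = Inf, ...) {
  simulate_ipd(object$model, hr = 1, n = nsim, cutoff = cutoff, seed = seed)
}

#' Deterministic small test fixture
#'
#' Simulated OS/PFS datasets for both arms (n per arm/endpoint) from the
#' baseline generating curves, plus a jittered copy of the baseline
#' parameter set, for integration tests.
#'
#' @param seed integer seed.
#' @param n records per arm/endpoint.
#' @return list with `ipd` (one `pseudo_ipd` data.frame) and `params`
#'   (a valid, perturbed `hcc_params`).
#' @export
make_fixture <- function(seed = 1, n = 200) {
  ps <- baseline_parameters()
  set.seed(seed)
  parts <- list(
    simulate_ipd(ps$os_tace, 1, n, 24, arm = "TACE", endpoint = "OS"),
    simulate_ipd(ps$os_tace, ps$hr_os$baseline, n, 24, arm = "FOLFOX_HAIC", endpoint = "OS"),
    simulate_ipd(ps$pfs_tace, 1, n, 24, arm = "TACE", endpoint = "PFS"),
    simulate_ipd(ps$pfs_tace, ps$hr_pfs$baseline, n, 24, arm = "FOLFOX_HAIC", endpoint = "PFS")
  )
  ipd <- do.call(rbind, parts)
  class(ipd) <- c("pseudo_ipd", "data.frame")
  jitter_unc <- function(p) {
    f <- stats::runif(1, 0.97, 1.03)
    v <- p$baseline * f
    if (p$distribution == "beta") v <- min(max(v, 0), 1)
    p$baseline <- min(max(v, p$low), p$high)
    p
  }
  reg <- parameter_registry(ps)
  for (i in seq_len(nrow(reg)))
    ps <- ps_set(ps, reg$path[[i]], jitter_unc(ps_get(ps, reg$path[[i]])))
  validate_parameters(ps)
  list(ipd = ipd, params = ps)
}
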