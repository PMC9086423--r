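test_that("inverse-transform sampling matches the generating distribution", {
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  pfs <- surv_model("lognormal", c(mu = 1.682471, sigma = 1.119812))
  n <- 1e5
  for (m in list(os, pfs)) {
    ipd <- simulate_ipd(m, hr = 1, n = n, cutoff = Inf, seed = 77)
    expect_equal(sum(ipd$event), n)   # no censoring without a cutoff
    # Kolmogorov-Smirnov distance against the closed-form CDF
    cdf <- function(t) 1 - survival_at(m, t)
    ks <- suppressWarnings(ks.test(ipd$time, cdf))$statistic
    expect_lt(unname(ks), 0.01)
    # empirical survival at the closed-form median is ~1/2
    expect_equal(mean(ipd$time > median(m)), 0.5, tolerance = 0.01)
  }
})

test_that("hazard ratios shift simulated survival as S^hr", {
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  ipd <- simulate_ipd(os, hr = 0.58, n = 4e4, cutoff = Inf, seed = 3)
  # S_new(median_base) = 0.5^0.58
  expect_equal(mean(ipd$time > median(os)), 0.5^0.58, tolerance = 0.01)
})

test_that("simulation is reproducible and censors at the cutoff", {
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  a <- simulate_ipd(os, 1, 500, cutoff = 24, seed = 10)
  b <- simulate_ipd(os, 1, 500, cutoff = 24, seed = 10)
  expect_identical(a, b)
  expect_true(all(a$time <= 24))
  expect_true(all(a$time[a$event == 0] == 24))
  expect_true(all(a$time > 0))
})

test_that("maximum likelihood recovers the generating parameters within 3 SE", {
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  ipd <- simulate_ipd(os, 1, 2000, cutoff = 24, seed = 42)
  fit <- fit_parametric(ipd, "log_logistic")
  expect_lt(abs(coef(fit)[["theta"]] - 0.00272126), 3 * fit$se[["theta"]])
  expect_lt(abs(coef(fit)[["kappa"]] - 2.184792), 3 * fit$se[["kappa"]])

  pfs <- surv_model("lognormal", c(mu = 1.682471, sigma = 1.119812))
  ipd2 <- simulate_ipd(pfs, 1, 2000, cutoff = 24, seed = 43)
  fit2 <- fit_parametric(ipd2, "lognormal")
  expect_lt(abs(coef(fit2)[["mu"]] - 1.682471), 3 * fit2$se[["mu"]])
  expect_lt(abs(coef(fit2)[["sigma"]] - 1.119812), 3 * fit2$se[["sigma"]])

  # the true family outfits the wrong one on data this size
  expect_gt(fit$loglik, fit_parametric(ipd, "lognormal")$loglik)
  expect_gt(fit2$loglik, fit_parametric(ipd2, "log_logistic")$loglik)
})

test_that("recovery bias shrinks as the sample grows", {
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  errs <- vapply(c(500, 2000, 8000), function(n) {
    ipd <- simulate_ipd(os, 1, n, cutoff = 60, seed = n)
    abs(coef(fit_parametric(ipd, "log_logistic"))[["kappa"]] - 2.184792)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("fits agree with an independent location-scale implementation", {
  skip_if_not_installed("survival")
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  ipd <- simulate_ipd(os, 1, 1500, cutoff = 36, seed = 9)
  fit <- fit_parametric(ipd, "log_logistic")
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = "loglogistic")
  # survreg: S(t) = 1/(1 + (t/exp(mu))^(1/scale)) => kappa = 1/scale,
  # theta = exp(-mu/scale)
  expect_equal(coef(fit)[["kappa"]], 1 / sr$scale, tolerance = 1e-3)
  expect_equal(coef(fit)[["theta"]],
               exp(-unname(coef(sr)) / sr$scale), tolerance = 1e-2)

  pfs <- surv_model("lognormal", c(mu = 1.682471, sigma = 1.119812))
  ipd2 <- simulate_ipd(pfs, 1, 1500, cutoff = 36, seed = 12)
  fit2 <- fit_parametric(ipd2, "lognormal")
  sr2 <- survival::survreg(survival::Surv(time, event) ~ 1, data = ipd2,
                           dist = "lognormal")
  expect_equal(coef(fit2)[["mu"]], unname(coef(sr2)), tolerance = 1e-4)
  expect_equal(coef(fit2)[["sigma"]], sr2$scale, tolerance = 1e-3)
})

test_that("fitting guards its preconditions", {
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  few <- simulate_ipd(os, 1, 30, cutoff = 0.2, seed = 1)  # nearly all censored
  expect_error(fit_parametric(few, "log_logistic"), "10 events")
})

test_that("fixtures are deterministic, valid, and run end-to-end", {
  f1 <- make_fixture(seed = 7)
  f2 <- make_fixture(seed = 7)
  expect_identical(f1, f2)
  expect_equal(nrow(f1$ipd), 4 * 200)
  expect_s3_class(validate_parameters(f1$params), "hcc_params")
  # refit one endpoint and run the full comparison on the jittered set
  os_fit <- fit_parametric(f1$ipd[f1$ipd$arm == "TACE" & f1$ipd$endpoint == "OS", ],
                           "log_logistic")
  psf <- f1$params
  psf$os_tace <- os_fit$model
  fit <- run_cea(psf)
  expect_true(is.finite(fit$comparison$incremental_cost))
  # model-object conveniences
  expect_length(predict(os_fit, c(6, 12)), 2)
  sim <- simulate(os_fit, nsim = 50, seed = 2)
  expect_equal(nrow(sim), 50)
})
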