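test_that("survival functions match their closed forms", {
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  pfs <- surv_model("lognormal", c(mu = 1.682471, sigma = 1.119812))

  expect_identical(survival_at(os, 0), 1)
  expect_identical(survival_at(pfs, 0), 1)

  # median via root-finding agrees with the closed forms
  med_root <- uniroot(function(t) survival_at(os, t) - 0.5, c(1, 100),
                      tol = 1e-12)$root
  expect_equal(med_root, (1 / 0.00272126)^(1 / 2.184792), tolerance = 1e-9)
  expect_equal(median(os), (1 / 0.00272126)^(1 / 2.184792), tolerance = 1e-12)
  expect_equal(survival_at(pfs, exp(1.682471)), 0.5, tolerance = 1e-12)
  expect_equal(median(pfs), exp(1.682471), tolerance = 1e-12)

  expect_error(survival_at(os, -1), "t must be")
  expect_error(surv_model("log_logistic", c(theta = -1, kappa = 2)), "positive")
  expect_error(surv_model("lognormal", c(mu = 0, sigma = 0)), "positive")
})

test_that("survival is non-increasing and bounded for random valid parameters", {
  set.seed(41)
  t <- sort(c(0, runif(60, 0, 400)))
  for (i in 1:25) {
    m <- if (i %% 2) {
      surv_model("log_logistic", c(theta = exp(runif(1, -8, 0)),
                                   kappa = runif(1, 0.3, 4)))
    } else {
      surv_model("lognormal", c(mu = runif(1, -1, 4), sigma = runif(1, 0.2, 2.5)))
    }
    s <- survival_at(m, t)
    expect_true(all(diff(s) <= 1e-15))
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(s[1], 1)
  }
})

test_that("hazard-ratio transform behaves as a proportional-hazards adjustment", {
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  S <- function(t) survival_at(os, t)
  t <- seq(0, 120, by = 3)

  expect_equal(apply_hr(S, 1)(t), S(t))                 # identity
  expect_equal(apply_hr(function(t) rep(0.5, length(t)), 0.58)(5),
               0.5^0.58)                                 # direct power
  expect_equal(log(apply_hr(S, 2)(t[-1])), 2 * log(S(t[-1])))
  # hr < 1 dominates pointwise, hr > 1 is dominated
  expect_true(all(apply_hr(S, 0.58)(t) >= S(t)))
  expect_true(all(apply_hr(S, 1.7)(t) <= S(t)))
  expect_error(apply_hr(S, 0), "positive")
  expect_error(apply_hr(S, -1), "positive")
})

test_that("per-cycle event probabilities follow the conditional-survival identity", {
  expect_equal(cycle_event_prob(function(t) rep(0.7, length(t)), 0, 1), 0)
  r <- 0.13
  S_exp <- function(t) exp(-r * t)
  expect_equal(cycle_event_prob(S_exp, 2, 3.5), 1 - exp(-r * 1.5), tolerance = 1e-12)
  # first 21-day cycle of the TACE OS curve, against brute-force evaluation
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  cyc_m <- 21 / 30.4375
  p <- cycle_event_prob(function(t) survival_at(os, t), 0, cyc_m)
  expect_true(p > 0 && p < 1)
  expect_equal(p, 1 - survival_at(os, cyc_m) / survival_at(os, 0))
  expect_equal(cycle_event_prob(function(t) rep(0, length(t)), 1, 2), 1)
  expect_error(cycle_event_prob(S_exp, 3, 2), "t_start")
})

test_that("annual-to-cycle probability conversion preserves boundary cases", {
  expect_equal(annual_to_cycle_prob(0, 21), 0)
  expect_equal(annual_to_cycle_prob(1, 21), 1)
  expect_equal(annual_to_cycle_prob(0.01956602, 21),
               1 - (1 - 0.01956602)^(21 / 365.25), tolerance = 1e-12)
  expect_error(annual_to_cycle_prob(1.2, 21), "\\[0, 1\\]")
})

test_that("life-table lookup is total and matches the tabulated bands", {
  lt <- china_life_table()
  expect_equal(annual_mortality(lt, 52), 0.01956602)
  expect_equal(annual_mortality(lt, 55), 0.030500498)
  expect_equal(annual_mortality(lt, 90), 1)
  ages <- seq(0, 120, by = 0.5)
  p <- annual_mortality(lt, ages)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  expect_equal(background_mortality(lt, 52, 21),
               1 - (1 - 0.01956602)^(21 / 365.25))
})

test_that("background blending multiplies independent risks", {
  lt0 <- life_table(c(0, 60), c(59, Inf), c(0, 1))
  os <- surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792))
  S_dis <- function(t) survival_at(os, t)
  t <- seq(0, 48, by = 6)
  # all-zero early mortality: blend changes nothing before the terminal band
  expect_equal(blend_background(S_dis, lt0, 30)(t), S_dis(t))
  lt <- china_life_table()
  S_all <- blend_background(S_dis, lt, 55)
  S_bg <- lifetable_survival(lt, 55)
  expect_equal(blend_background(function(t) rep(1, length(t)), lt, 55)(t), S_bg(t))
  expect_true(all(S_all(t) <= pmin(S_dis(t), S_bg(t)) + 1e-15))
  # piecewise-constant-hazard survival agrees with an independent integration
  t_y <- c(0.5, 3, 7.2, 20, 29.9)
  expect_equal(S_bg(t_y * 365.25 / 30.4375),
               bg_survival_oracle(lt, 55, t_y), tolerance = 1e-10)
})
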