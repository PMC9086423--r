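# every parameter row of the published input table, as label / value /
# accessor into the parameter set
table1_manifest <- function(ps) {
  list(
    list("OS curve theta", 0.00272126, ps$os_tace$params[["theta"]]),
    list("OS curve kappa", 2.184792, ps$os_tace$params[["kappa"]]),
    list("PFS curve mu", 1.682471, ps$pfs_tace$params[["mu"]]),
    list("PFS curve sigma", 1.119812, ps$pfs_tace$params[["sigma"]]),
    list("HR OS", 0.58, ps$hr_os$baseline),
    list("HR PFS", 0.57, ps$hr_pfs$baseline),
    list("hepatectomy after FOLFOX-HAIC", 0.24,
         ps$strategies$FOLFOX_HAIC$hepatectomy_proportion$baseline),
    list("hepatectomy after TACE", 0.12,
         ps$strategies$TACE$hepatectomy_proportion$baseline),
    list("recurrence", 0.19, ps$recurrence_prob$baseline),
    list("BSC after FOLFOX-HAIC", 0.95,
         ps$strategies$FOLFOX_HAIC$subsequent_mix$BSC$baseline),
    list("BSC after TACE", 0.87, ps$strategies$TACE$subsequent_mix$BSC$baseline),
    list("TACE after FOLFOX-HAIC", 0.05,
         ps$strategies$FOLFOX_HAIC$subsequent_mix$crossover$baseline),
    list("HAIC after TACE", 0.13, ps$strategies$TACE$subsequent_mix$crossover$baseline),
    list("ALT incidence HAIC", 0.08,
         ps$strategies$FOLFOX_HAIC$ae_incidence$elevated_alt$baseline),
    list("AST incidence HAIC", 0.18,
         ps$strategies$FOLFOX_HAIC$ae_incidence$elevated_ast$baseline),
    list("vomiting incidence HAIC", 0.06,
         ps$strategies$FOLFOX_HAIC$ae_incidence$vomiting$baseline),
    list("ALT incidence TACE", 0.19,
         ps$strategies$TACE$ae_incidence$elevated_alt$baseline),
    list("AST incidence TACE", 0.29,
         ps$strategies$TACE$ae_incidence$elevated_ast$baseline),
    list("vomiting incidence TACE", 0.05,
         ps$strategies$TACE$ae_incidence$vomiting$baseline),
    list("utility PFD", 0.76, ps$utilities$PFD$baseline),
    list("utility PD", 0.68, ps$utilities$PD$baseline),
    list("ALT/AST disutility", 0, ps$ae_disutilities$elevated_alt_ast$baseline),
    list("vomiting disutility", 0.05, ps$ae_disutilities$vomiting$baseline),
    list("ALT/AST event cost", 43, ps$ae_costs$elevated_alt_ast$baseline),
    list("vomiting event cost", 49, ps$ae_costs$vomiting$baseline),
    list("discount rate", 0.03, ps$discount_rate_annual$baseline),
    list("oxaliplatin cost", 426,
         ps$strategies$FOLFOX_HAIC$per_session_costs$oxaliplatin$baseline),
    list("fluorouracil cost", 524,
         ps$strategies$FOLFOX_HAIC$per_session_costs$fluorouracil$baseline),
    list("leucovorin cost", 24,
         ps$strategies$FOLFOX_HAIC$per_session_costs$leucovorin$baseline),
    list("HAIC cost", 1850, ps$strategies$FOLFOX_HAIC$per_session_costs$HAIC$baseline),
    list("TACE cost", 1929, ps$strategies$TACE$per_session_costs$TACE$baseline),
    list("hepatectomy cost", 9022, ps$shared_costs$hepatectomy$baseline),
    list("hospitalization cost", 384,
         ps$shared_costs$hospitalization_per_cycle$baseline),
    list("BSC cost", 363, ps$shared_costs$bsc_per_cycle$baseline)
  )
}

test_that("bundled baseline carries every published input value", {
  ps <- baseline_parameters()
  for (row in table1_manifest(ps))
    expect_equal(row[[3]], row[[2]], info = row[[1]])
  # spot-check ranges and distribution families
  expect_equal(c(ps$hr_os$low, ps$hr_os$high), c(0.45, 0.75))
  expect_identical(ps$hr_os$distribution, "lognormal")
  expect_identical(ps$utilities$PD$distribution, "beta")
  expect_identical(ps$shared_costs$bsc_per_cycle$distribution, "gamma")
  expect_identical(ps$discount_rate_annual$distribution, "uniform")
  expect_equal(ps$structural$cycle_length_days, 21)
  expect_equal(ps$structural$wtp_per_qaly, 30552)
  expect_equal(ps$strategies$FOLFOX_HAIC$n_sessions, 3.6)
  expect_equal(ps$strategies$TACE$session_interval_days, 42)
  # background mortality table
  expect_equal(nrow(ps$life_table), 19)
  expect_equal(ps$life_table$annual_prob[19], 1)
})

test_that("default ranges span +/-20% of baseline, clamped to support", {
  p <- default_range(uncertain(1850, distribution = "gamma"))
  expect_equal(c(p$low, p$high), c(1480, 2220))
  p0 <- default_range(uncertain(0, distribution = "gamma"))
  expect_equal(c(p0$low, p0$high), c(0, 0))
  pb <- default_range(uncertain(0.95, distribution = "beta"))
  expect_equal(pb$low, 0.76)
  expect_equal(pb$high, 1)   # 1.14 clamped to the beta support
})

test_that("config files round-trip field-for-field", {
  ps <- baseline_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(ps, path)
  ps2 <- read_config(path)
  expect_equal(ps2, ps, tolerance = 1e-12)
  # bundled asset equals the in-code baseline
  expect_equal(read_config(baseline_config_path()), ps, tolerance = 1e-12)
})

test_that("validation names the offending field", {
  ps <- baseline_parameters()
  ps$utilities$PD$baseline <- 1.2
  expect_error(validate_parameters(ps), "utilities.*PD|Utility PD")
  ps <- baseline_parameters()
  ps$hr_pfs <- NULL
  expect_error(validate_parameters(ps), "hr_pfs")
  ps <- baseline_parameters()
  ps$hr_os$low <- 0.7
  ps$hr_os$baseline <- 0.6
  expect_error(validate_parameters(ps), "low <= baseline")
  ps <- baseline_parameters()
  ps$structural$background_mode <- "additive"
  expect_error(validate_parameters(ps), "background_mode")
  # config-level: missing field reported by name
  path <- withr::local_tempfile(fileext = ".yaml")
  ps <- baseline_parameters()
  write_config(ps, path)
  cfg <- yaml::read_yaml(path)
  cfg$hr_pfs <- NULL
  yaml::write_yaml(cfg, path)
  expect_error(read_config(path), "hr_pfs")
})
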