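write_manifest <- function(outdir, command, config, seed = NULL, files) {
  manifest <- list(
    command = command,
    config = config,
    config_md5 = unname(tools::md5sum(config)),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("haiccea")),
    outputs = files
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

load_config <- function(config) {
  if (is.null(config)) baseline_config_path() else config
}

#' Path to the bundled baseline configuration file
#' @return file path of the YAML config shipped with the package.
#' @export
baseline_config_path <- function() {
  system.file("extdata", "baseline.yaml", package = "haiccea", mustWork = TRUE)
}

#' Base-case report: traces, per-strategy results, incremental comparison
#'
#' Writes `trace_<strategy>.csv`, `cea_results.csv` (one row per strategy
#' and cost component), `icer.csv` and a run manifest to `outdir`.
#'
#' @param config path to a YAML parameter config; `NULL` for the bundled
#'   baseline.
#' @param outdir output directory (created if needed).
#' @return the `hcc_cea` object, invisibly.
#' @export
report_basecase <- function(config = NULL, outdir) {
  config <- load_config(config)
  ps <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fit <- run_cea(ps)
  files <- character()
  for (s in strategy_names()) {
    f <- file.path(outdir, paste0("trace_", s, ".csv"))
    utils::write.csv(as.data.frame(fit[[s]]$trace), f, row.names = FALSE)
    files <- c(files, f)
  }
  sm <- summary(fit)
  res <- data.frame(strategy = rownames(sm$cost_breakdown), sm$cost_breakdown,
                    qalys = sm$strategies[, "qalys"], lys = sm$strategies[, "lys"])
  f <- file.path(outdir, "cea_results.csv")
  utils::write.csv(res, f, row.names = FALSE)
  cmp <- fit$comparison
  f2 <- file.path(outdir, "icer.csv")
  utils::write.csv(data.frame(incremental_cost = cmp$incremental_cost,
                              incremental_qalys = cmp$incremental_qalys,
                              icer = cmp$icer, wtp = cmp$wtp, nmb = cmp$nmb,
                              cost_effective = cmp$cost_effective), f2,
                   row.names = FALSE)
  write_manifest(outdir, "basecase", config, files = c(files, f, f2))
  invisible(fit)
}

#' One-way sensitivity report (tornado table)
#' @inheritParams report_basecase
#' @return the tornado data.frame, invisibly.
#' @export
report_owsa <- function(config = NULL, outdir) {
  config <- load_config(config)
  ps <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tor <- one_way_sa(ps)
  f <- file.path(outdir, "tornado.csv")
  utils::write.csv(tor, f, row.names = FALSE)
  write_manifest(outdir, "owsa", config, files = f)
  invisible(tor)
}

#' Probabilistic sensitivity report (samples, CEAC, summary)
#' @inheritParams report_basecase
#' @param n_iter Monte-Carlo iterations.
#' @param seed integer seed.
#' @return the `hcc_psa` object, invisibly.
#' @export
report_psa <- function(config = NULL, outdir, n_iter = 10000, seed = 2021) {
  if (n_iter < 1) stop("report_psa: n_iter must be >= 1")
  config <- load_config(config)
  ps <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(ps, n_iter = n_iter, seed = seed)
  f1 <- file.path(outdir, "psa_samples.csv")
  utils::write.csv(psa$samples, f1, row.names = FALSE)
  f2 <- file.path(outdir, "ceac.csv")
  utils::write.csv(psa$ceac, f2, row.names = FALSE)
  f3 <- file.path(outdir, "psa_summary.csv")
  utils::write.csv(data.frame(n_iter = psa$n_iter, seed = psa$seed,
                              wtp = psa$wtp, prob_ce = psa$prob_ce,
                              mean_d_cost = psa$mean_d_cost,
                              mean_d_qaly = psa$mean_d_qaly), f3,
                   row.names = FALSE)
  write_manifest(outdir, "psa", config, seed = seed, files = c(f1, f2, f3))
  invisible(psa)
}

#' Subgroup report
#' @inheritParams report_psa
#' @param n_psa PSA iterations per subgroup (0 to report deterministic
#'   ICERs only).
#' @return the subgroup data.frame, invisibly.
#' @export
report_subgroups <- function(config = NULL, outdir, n_psa = 2000, seed = 2021) {
  config <- load_config(config)
  ps <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- subgroup_analysis(ps, n_psa = n_psa, seed = seed)
  f <- file.path(outdir, "subgroups.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  write_manifest(outdir, "subgroups", config, seed = seed, files = f)
  invisible(tab)
}

#' Simulated-IPD report
#'
#' Simulates survival records for both arms and endpoints from the
#' configured generating curves and writes them as CSV.
#' @inheritParams report_psa
#' @param n patients per arm/endpoint.
#' @param cutoff administrative censoring time (months).
#' @export
report_simulated_ipd <- function(config = NULL, outdir, n = 200, cutoff = 24,
                                 seed = 2021) {
  config <- load_config(config)
  ps <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ipd <- rbind(
    simulate_ipd(ps$os_tace, 1, n, cutoff, arm = "TACE", endpoint = "OS"),
    simulate_ipd(ps$os_tace, ps$hr_os$baseline, n, cutoff, arm = "FOLFOX_HAIC", endpoint = "OS"),
    simulate_ipd(ps$pfs_tace, 1, n, cutoff, arm = "TACE", endpoint = "PFS"),
    simulate_ipd(ps$pfs_tace, ps$hr_pfs$baseline, n, cutoff, arm = "FOLFOX_HAIC", endpoint = "PFS"))
  f <- file.path(outdir, "simulated_ipd.csv")
  utils::write.csv(ipd, f, row.names = FALSE)
  write_manifest(outdir, "simulate-ipd", config, seed = seed, files = f)
  invisible(ipd)
}
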