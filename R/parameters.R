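#' Uncertain model parameter
#'
#' A scalar input with a baseline value, a plausibility range (typically a
#' 95\% CI from the literature, otherwise +/-20\% of baseline), and the
#' distribution family used for probabilistic sensitivity analysis.
#'
#' @param baseline point estimate used in the deterministic base case.
#' @param low,high range bounds; `NA` to have [default_range()] fill them.
#' @param distribution one of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"uniform"`, `"fixed"`.
#' @return object of class `uncertain`.
#' @export
uncertain <- function(baseline, low = NA_real_, high = NA_real_,
                      distribution = c("fixed", "beta", "gamma", "lognormal", "uniform")) {
  distribution <- match.arg(distribution)
  structure(list(baseline = baseline, low = low, high = high,
                 distribution = distribution),
            class = "uncertain")
}

#' @export
print.uncertain <- function(x, ...) {
  cat(sprintf("%g [%g, %g] (%s)\n", x$baseline, x$low, x$high, x$distribution))
  invisible(x)
}

#' Fill a missing uncertainty range with +/-20\% of baseline
#'
#' Ranges not reported in the literature are assumed to span 80\%-120\% of
#' the baseline value, clamped to the distribution's support (beta: `[0, 1]`;
#' gamma: non-negative).
#'
#' @param p an [uncertain] parameter.
#' @return the parameter with `low`/`high` filled where they were `NA`.
#' @export
default_range <- function(p) {
  stopifnot(inherits(p, "uncertain"))
  if (is.na(p$low)) p$low <- 0.8 * p$baseline
  if (is.na(p$high)) p$high <- 1.2 * p$baseline
  if (p$distribution == "beta") {
    p$low <- min(max(p$low, 0), 1)
    p$high <- min(max(p$high, 0), 1)
  }
  if (p$distribution == "gamma") {
    p$low <- max(p$low, 0)
  }
  p
}

strategy_names <- function() c("FOLFOX_HAIC", "TACE")

#' Baseline model parameter set
#'
#' The complete bundled input vector for the cost-effectiveness model:
#' TACE survival-curve parameters (log-logistic OS, lognormal PFS), hazard
#' ratios of FOLFOX-HAIC versus TACE, hepatectomy and subsequent-treatment
#' proportions, post-hepatectomy recurrence, grade >= 3
#' adverse-event incidences with shared unit costs and disutilities, health
#' utilities, per-cycle and one-off costs (USD), the 3\% annual discount
#' rate, the Chinese age-banded background-mortality life table, and
#' structural settings (21-day cycles, start age 55, 35-year horizon,
#' willingness-to-pay $30,552/QALY, background-mortality mode,
#' recurrence-probability basis, half-cycle correction flag).
#'
#' @return object of class `hcc_params` (a named list; see the methods
#'   vignette for the full schema).
#' @export
baseline_parameters <- function() {
  ps <- list(
    os_tace = surv_model("log_logistic", c(theta = 0.00272126, kappa = 2.184792)),
    pfs_tace = surv_model("lognormal", c(mu = 1.682471, sigma = 1.119812)),
    hr_os = uncertain(0.58, 0.45, 0.75, "lognormal"),
    hr_pfs = uncertain(0.57, 0.45, 0.72, "lognormal"),
    recurrence_prob = uncertain(0.19, 0.15, 0.20, "beta"),
    utilities = list(
      PFD = uncertain(0.76, 0.61, 0.91, "beta"),
      RFD = uncertain(0.76, 0.61, 0.91, "beta"),
      PD = uncertain(0.68, 0.54, 0.82, "beta")
    ),
    ae_costs = list(            # USD per event, shared across arms
      elevated_alt_ast = uncertain(43, 35, 52, "gamma"),
      vomiting = uncertain(49, 39, 59, "gamma")
    ),
    ae_disutilities = list(     # utility decrement, shared across arms
      elevated_alt_ast = uncertain(0, 0, 0, "fixed"),
      vomiting = uncertain(0.05, 0.04, 0.06, "beta")
    ),
    shared_costs = list(        # USD
      hepatectomy = uncertain(9022, 7218, 10827, "gamma"),
      hospitalization_per_cycle = uncertain(384, 307, 460, "gamma"),
      bsc_per_cycle = uncertain(363, 291, 436, "gamma")
    ),
    discount_rate_annual = uncertain(0.03, 0.01, 0.05, "uniform"),
    life_table = china_life_table(),
    strategies = list(
      FOLFOX_HAIC = list(
        name = "FOLFOX_HAIC",
        per_session_costs = list(     # USD per 21-day treatment cycle
          oxaliplatin = uncertain(426, 340, 511, "gamma"),
          fluorouracil = uncertain(524, 419, 629, "gamma"),
          leucovorin = uncertain(24, 19, 29, "gamma"),
          HAIC = uncertain(1850, 1480, 2220, "gamma")
        ),
        n_sessions = 3.6,             # mean HAIC administrations per patient
        session_interval_days = 21,   # once every three weeks
        hospitalize_during_treatment = TRUE,   # 24-h infusion admissions
        hepatectomy_proportion = uncertain(0.24, 0.19, 0.29, "beta"),
        ae_incidence = list(
          elevated_alt = uncertain(0.08, 0.06, 0.10, "beta"),
          elevated_ast = uncertain(0.18, 0.14, 0.22, "beta"),
          vomiting = uncertain(0.06, 0.05, 0.07, "beta")
        ),
        subsequent_mix = list(
          BSC = uncertain(0.95, 0.76, 1.14, "beta"),
          crossover = uncertain(0.05, 0.04, 0.06, "beta")
        )
      ),
      TACE = list(
        name = "TACE",
        per_session_costs = list(
          TACE = uncertain(1929, 1543, 2315, "gamma")
        ),
        n_sessions = 2,               # mean TACE procedures per patient
        session_interval_days = 42,   # once every six weeks
        hospitalize_during_treatment = FALSE,  # procedure cost is admission-inclusive
        hepatectomy_proportion = uncertain(0.12, 0.10, 0.14, "beta"),
        ae_incidence = list(
          elevated_alt = uncertain(0.19, 0.15, 0.23, "beta"),
          elevated_ast = uncertain(0.29, 0.23, 0.35, "beta"),
          vomiting = uncertain(0.05, 0.04, 0.06, "beta")
        ),
        subsequent_mix = list(
          BSC = uncertain(0.87, 0.70, 1.04, "beta"),
          crossover = uncertain(0.13, 0.10, 0.16, "beta")
        )
      )
    ),
    structural = list(
      cycle_length_days = 21,
      start_age_years = 55,
      horizon_years = 35,
      wtp_per_qaly = 30552,
      half_cycle_correction = FALSE,
      background_mode = "floor",     # or "multiplicative"
      recurrence_basis = "five_year",# or "annual"
      rfd_mortality = "os_floor"     # or "background"
    )
  )
  class(ps) <- "hcc_params"
  validate_parameters(ps)
  ps
}

#' Chinese background-mortality life table
#'
#' Age-banded annual probabilities of death used for background mortality;
#' the terminal 85+ band is absorbing (annual probability 1).
#' @return a [life_table].
#' @export
china_life_table <- function() {
  life_table(
    age_low = c(0, 1, seq(5, 85, by = 5)),
    age_high = c(0, 4, seq(9, 84, by = 5), Inf),
    annual_prob = c(0.006763658, 0.001144414, 0.000924507, 0.000969999,
                    0.00179698, 0.002810805, 0.003052746, 0.004239707,
                    0.006187994, 0.009315495, 0.012327216, 0.01956602,
                    0.030500498, 0.048778564, 0.078138957, 0.137236768,
                    0.221445846, 0.371374039, 1)
  )
}

validate_uncertain <- function(p, field) {
  if (!inherits(p, "uncertain"))
    stop("parameter '", field, "' is not an uncertain() value", call. = FALSE)
  for (f in c("baseline", "low", "high"))
    if (is.null(p[[f]]) || !is.numeric(p[[f]]))
      stop("parameter '", field, "': missing numeric '", f, "'", call. = FALSE)
  if (!is.na(p$low) && !is.na(p$high)) {
    if (p$low > p$baseline + 1e-12 || p$baseline > p$high + 1e-12)
      stop("parameter '", field, "': requires low <= baseline <= high", call. = FALSE)
  }
  if (p$distribution == "beta" && (p$baseline < 0 || p$baseline > 1))
    stop("parameter '", field, "': beta-distributed baseline must be in [0, 1]", call. = FALSE)
  if (p$distribution == "gamma" && p$baseline < 0)
    stop("parameter '", field, "': gamma-distributed baseline must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Validate a parameter set
#'
#' Checks structural completeness (every required field present) and the
#' per-parameter invariants (`low <= baseline <= high`, distribution
#' support). Errors name the offending field.
#'
#' @param ps an `hcc_params` object (or a plain list with the same schema).
#' @return `ps`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(ps) {
  required <- c("os_tace", "pfs_tace", "hr_os", "hr_pfs", "recurrence_prob",
                "utilities", "ae_costs", "ae_disutilities", "shared_costs",
                "discount_rate_annual", "life_table", "strategies", "structural")
  missing <- setdiff(required, names(ps))
  if (length(missing))
    stop("parameter set is missing field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (m in c("os_tace", "pfs_tace"))
    if (!inherits(ps[[m]], "surv_model")) stop("'", m, "' must be a surv_model", call. = FALSE)
  reg <- parameter_registry(ps)
  for (i in seq_len(nrow(reg)))
    validate_uncertain(ps_get(ps, reg$path[[i]]), reg$label[i])
  for (s in strategy_names()) {
    st <- ps$strategies[[s]]
    if (is.null(st)) stop("strategies must include '", s, "'", call. = FALSE)
    if (!is.numeric(st$n_sessions) || st$n_sessions <= 0)
      stop("strategy ", s, ": n_sessions must be > 0", call. = FALSE)
    if (!is.numeric(st$session_interval_days) || st$session_interval_days <= 0)
      stop("strategy ", s, ": session_interval_days must be > 0", call. = FALSE)
  }
  lt <- ps$life_table
  if (!inherits(lt, "life_table")) stop("'life_table' must be a life_table", call. = FALSE)
  if (lt$annual_prob[nrow(lt)] != 1)
    stop("life_table: terminal band must have annual probability 1", call. = FALSE)
  st <- ps$structural
  for (f in c("cycle_length_days", "start_age_years", "horizon_years", "wtp_per_qaly"))
    if (is.null(st[[f]]) || !is.numeric(st[[f]]) || st[[f]] <= 0)
      stop("structural$", f, " must be a positive number", call. = FALSE)
  if (!(st$background_mode %||% "floor") %in% c("floor", "multiplicative"))
    stop("structural$background_mode must be 'floor' or 'multiplicative'", call. = FALSE)
  if (!(st$recurrence_basis %||% "five_year") %in% c("five_year", "annual"))
    stop("structural$recurrence_basis must be 'five_year' or 'annual'", call. = FALSE)
  if (!(st$rfd_mortality %||% "os_floor") %in% c("os_floor", "background"))
    stop("structural$rfd_mortality must be 'os_floor' or 'background'", call. = FALSE)
  invisible(ps)
}

# --- flat registry of every uncertain parameter (used by validation, the
# --- tornado analysis and PSA sampling). `path` indexes into the nested list.
parameter_registry <- function(ps) {
  rows <- list(
    list("HR OS (FOLFOX-HAIC vs TACE)", c("hr_os")),
    list("HR PFS (FOLFOX-HAIC vs TACE)", c("hr_pfs")),
    list("Recurrence after hepatectomy", c("recurrence_prob")),
    list("Utility PFD", c("utilities", "PFD")),
    list("Utility RFD", c("utilities", "RFD")),
    list("Utility PD", c("utilities", "PD")),
    list("AE cost: elevated ALT/AST", c("ae_costs", "elevated_alt_ast")),
    list("AE cost: vomiting", c("ae_costs", "vomiting")),
    list("AE disutility: elevated ALT/AST", c("ae_disutilities", "elevated_alt_ast")),
    list("AE disutility: vomiting", c("ae_disutilities", "vomiting")),
    list("Cost of hepatectomy", c("shared_costs", "hepatectomy")),
    list("Cost of hospitalization per cycle", c("shared_costs", "hospitalization_per_cycle")),
    list("Cost of BSC per cycle", c("shared_costs", "bsc_per_cycle")),
    list("Discount rate", c("discount_rate_annual"))
  )
  for (s in strategy_names()) {
    st <- ps$strategies[[s]]
    for (d in names(st$per_session_costs))
      rows[[length(rows) + 1L]] <- list(paste0("Cost of ", d, " (", s, ")"),
                                        c("strategies", s, "per_session_costs", d))
    rows[[length(rows) + 1L]] <- list(paste0("Proportion hepatectomy after ", s),
                                      c("strategies", s, "hepatectomy_proportion"))
    for (a in names(st$ae_incidence))
      rows[[length(rows) + 1L]] <- list(paste0("Incidence ", a, " (", s, ")"),
                                        c("strategies", s, "ae_incidence", a))
    for (m in names(st$subsequent_mix))
      rows[[length(rows) + 1L]] <- list(paste0("Proportion ", m, " after ", s),
                                        c("strategies", s, "subsequent_mix", m))
  }
  data.frame(label = vapply(rows, `[[`, "", 1L),
             path = I(lapply(rows, `[[`, 2L)),
             stringsAsFactors = FALSE)
}

ps_get <- function(ps, path) {
  x <- ps
  for (k in path) x <- x[[k]]
  x
}

ps_set <- function(ps, path, value) {
  expr <- Reduce(function(acc, k) call("[[", acc, k), path, init = quote(ps))
  eval(call("<-", expr, value))
  ps
}

# set only the baseline (point) value of an uncertain parameter
ps_set_baseline <- function(ps, path, value) {
  p <- ps_get(ps, path)
  p$baseline <- value
  ps_set(ps, path, p)
}

#' @export
print.hcc_params <- function(x, ...) {
  reg <- parameter_registry(x)
  cat("HCC cost-effectiveness parameter set\n")
  cat(sprintf("  TACE OS:  log-logistic (median %.2f months)\n", median(x$os_tace)))
  cat(sprintf("  TACE PFS: lognormal    (median %.2f months)\n", median(x$pfs_tace)))
  cat(sprintf("  %d uncertain parameters; cycle %g days; start age %g; horizon %g years; WTP $%s/QALY\n",
              nrow(reg), x$structural$cycle_length_days, x$structural$start_age_years,
              x$structural$horizon_years, format(x$structural$wtp_per_qaly, big.mark = ",")))
  invisible(x)
}

# ---- config (YAML) serialization ------------------------------------------

unc_to_list <- function(p) list(baseline = p$baseline, low = p$low, high = p$high,
                                distribution = p$distribution)
unc_from_list <- function(x, field) {
  if (is.null(x$baseline)) stop("config: parameter '", field, "' missing baseline", call. = FALSE)
  uncertain(x$baseline, x$low %||% NA_real_, x$high %||% NA_real_,
            x$distribution %||% "fixed")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

node_to_plain <- function(x) {
  if (inherits(x, "uncertain")) return(unc_to_list(x))
  if (inherits(x, "surv_model")) return(list(family = x$family, params = as.list(x$params)))
  if (inherits(x, "life_table"))
    return(list(age_low = x$age_low,
                age_high = ifelse(is.infinite(x$age_high), -1, x$age_high),
                annual_prob = x$annual_prob))
  if (is.list(x)) return(lapply(x, node_to_plain))
  x
}

#' Write a parameter set to a YAML configuration file
#'
#' @param ps an `hcc_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_config()]
#' @export
write_config <- function(ps, path) {
  validate_parameters(ps)
  yaml::write_yaml(node_to_plain(unclass(ps)), path, precision = 15)
  invisible(path)
}

#' Read a parameter set from a YAML configuration file
#'
#' The schema mirrors [baseline_parameters()]; [validate_parameters()] is
#' applied, so schema violations and invariant breaches (for example a
#' utility above 1 under a beta distribution, or a missing hazard ratio)
#' raise an error naming the offending field.
#'
#' @param path config file path.
#' @return an `hcc_params` object; `read_config(write_config(ps))` is
#'   field-for-field identical to `ps`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("os_tace", "pfs_tace", "hr_os", "hr_pfs", "recurrence_prob",
                "utilities", "ae_costs", "ae_disutilities", "shared_costs",
                "discount_rate_annual", "life_table", "strategies", "structural")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("config is missing field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  ps <- raw
  for (m in c("os_tace", "pfs_tace"))
    ps[[m]] <- surv_model(raw[[m]]$family, unlist(raw[[m]]$params))
  hi <- unlist(raw$life_table$age_high)
  hi[hi < 0] <- Inf
  ps$life_table <- life_table(unlist(raw$life_table$age_low), hi,
                              unlist(raw$life_table$annual_prob))
  rebuild <- function(node, prefix) {
    if (is.list(node) && !is.null(node$distribution) && !is.null(node$baseline))
      return(unc_from_list(node, prefix))
    if (is.list(node))
      return(stats::setNames(lapply(names(node), function(k)
        rebuild(node[[k]], paste(prefix, k, sep = "."))), names(node)))
    node
  }
  for (f in c("hr_os", "hr_pfs", "recurrence_prob", "utilities", "ae_costs",
              "ae_disutilities", "shared_costs", "discount_rate_annual", "strategies"))
    ps[[f]] <- rebuild(raw[[f]], f)
  ps$structural$half_cycle_correction <- isTRUE(ps$structural$half_cycle_correction)
  class(ps) <- "hcc_params"
  validate_parameters(ps)
  ps
}
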