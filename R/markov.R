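#' Run the cohort state-transition trace for one strategy
#'
#' Simulates the four-state cohort model (progression-free disease PFD,
#' recurrence-free disease after hepatectomy RFD, progressed disease PD,
#' Death) on 21-day cycles over the model horizon.
#'
#' The arm-specific curves are built from the TACE baseline fits: TACE uses
#' them directly, FOLFOX-HAIC applies the OS/PFS hazard ratios as
#' \eqn{S^{hr}}; PFS is capped at OS pointwise. Background mortality enters
#' per `structural$background_mode`: `"floor"` (default) takes the
#' per-cycle exit probability as the larger of the disease-specific and
#' life-table risks; `"multiplicative"` multiplies the curves by life-table
#' background survival (independent competing risks). Per-cycle transition
#' probabilities are derived from the resulting all-cause curves so that
#' with a hepatectomy proportion of zero the chain reproduces the
#' partitioned-survival occupancy (PFD = S_PFS, PD = S_OS - S_PFS,
#' Death = 1 - S_OS) exactly at every cycle boundary. Deaths each cycle are
#' attributed to PFD occupants at the background-mortality rate first and
#' the remainder to PD occupants; when the PD pool is too small to absorb
#' them (early cycles) the excess is drawn from PFD directly. At the end of
#' first-line treatment (`n_sessions * session_interval_days`, rounded up
#' to a cycle boundary) a fraction `hepatectomy_proportion` of the
#' progression-free cohort moves to RFD. RFD occupants face a
#' constant-hazard recurrence risk derived from the cumulative recurrence
#' probability (5-year basis by default per
#' `structural$recurrence_basis`), and a per-cycle death risk set by
#' `structural$rfd_mortality`: `"os_floor"` (default) keeps the cohort's
#' all-cause OS-based risk, floored at background mortality -- the trial OS
#' curves already include the hepatectomy patients, so this avoids
#' double-counting the surgical survival benefit -- while `"background"`
#' treats hepatectomy as curative (background mortality only). On
#' recurrence they enter PD, where they exit at the model's PD death
#' hazard (floored at background mortality).
#'
#' @param ps an `hcc_params` parameter set.
#' @param strategy `"FOLFOX_HAIC"` or `"TACE"`.
#' @return object of class `cohort_trace`: a list with `time_months`,
#'   `age_years`, an `occupancy` matrix (cycles x states PFD/RFD/PD/Death,
#'   rows summing to 1), and an `entrants` matrix of per-cycle new entries
#'   into RFD and PD.
#' @export
run_trace <- function(ps, strategy = strategy_names()) {
  strategy <- match.arg(strategy)
  st <- ps$structural
  cyc_d <- st$cycle_length_days
  cyc_m <- cyc_d / DAYS_PER_MONTH
  n_cyc <- ceiling(st$horizon_years * DAYS_PER_YEAR / cyc_d)
  t_m <- (0:n_cyc) * cyc_m                          # cycle-boundary times, months
  t_y <- (0:n_cyc) * cyc_d / DAYS_PER_YEAR
  age <- st$start_age_years + t_y

  hr_os <- if (strategy == "FOLFOX_HAIC") ps$hr_os$baseline else 1
  hr_pfs <- if (strategy == "FOLFOX_HAIC") ps$hr_pfs$baseline else 1
  s_os_d <- survival_at(ps$os_tace, t_m, hr = hr_os)
  s_pfs_d <- pmin(survival_at(ps$pfs_tace, t_m, hr = hr_pfs), s_os_d)  # PFS cannot exceed OS

  p_bg <- background_mortality(ps$life_table, age[1:n_cyc], cyc_d)
  bg_mode <- st$background_mode %||% "floor"
  if (bg_mode == "multiplicative") {
    S_bg <- lifetable_survival(ps$life_table, st$start_age_years)(t_m)
    s_os <- s_os_d * S_bg
    s_pfs <- s_pfs_d * S_bg
  } else if (bg_mode == "floor") {
    # per-cycle exit probability is the larger of the disease-specific and
    # background risks (all-cause mortality can never fall below background)
    cond <- function(s) {
      q <- ifelse(s[1:n_cyc] > 0, 1 - s[2:(n_cyc + 1)] / s[1:n_cyc], 1)
      cumprod(c(1, 1 - pmax(q, p_bg)))
    }
    s_os <- cond(s_os_d)
    s_pfs <- pmin(cond(s_pfs_d), s_os)
  } else stop("run_trace: unknown structural$background_mode '", bg_mode, "'")

  # partitioned-survival quantities at cycle boundaries
  pfd_part <- s_pfs
  pd_part <- s_os - s_pfs
  q_pfs <- ifelse(pfd_part[1:n_cyc] > 0,
                  1 - s_pfs[2:(n_cyc + 1)] / pfd_part[1:n_cyc], 1)
  deaths <- s_os[1:n_cyc] - s_os[2:(n_cyc + 1)]

  # attribute deaths: PFD at background rate, remainder to PD; overflow back
  # to PFD when the PD pool cannot absorb it. Exact by construction.
  d_pfd <- pmin(p_bg, q_pfs)
  rem <- deaths - pfd_part[1:n_cyc] * d_pfd
  h_pd <- numeric(n_cyc)
  for (k in seq_len(n_cyc)) {
    if (pd_part[k] > 1e-12) {
      h <- rem[k] / pd_part[k]
      if (h > 1) {
        if (pfd_part[k] > 0)
          d_pfd[k] <- min(q_pfs[k], d_pfd[k] + (rem[k] - pd_part[k]) / pfd_part[k])
        h <- 1
      } else if (h < 0) {
        d_pfd[k] <- if (pfd_part[k] > 0) min(q_pfs[k], max(deaths[k], 0) / pfd_part[k]) else 0
        h <- 0
      }
      h_pd[k] <- h
    } else {
      d_pfd[k] <- if (pfd_part[k] > 0) min(q_pfs[k], max(deaths[k], 0) / pfd_part[k]) else 0
      h_pd[k] <- p_bg[k]
    }
  }
  p_to_pd <- pmax(q_pfs - d_pfd, 0)

  # recurrence after hepatectomy: constant hazard from the cumulative
  # recurrence probability (5-year basis by default, annual available)
  basis_years <- switch(st$recurrence_basis %||% "five_year",
                        five_year = 5, annual = 1,
                        stop("run_trace: unknown structural$recurrence_basis"))
  r_annual <- -log(1 - ps$recurrence_prob$baseline) / basis_years
  p_rec <- 1 - exp(-r_annual * cyc_d / DAYS_PER_YEAR)

  # post-hepatectomy mortality: the trial OS curves already include the
  # patients who underwent hepatectomy, so by default RFD occupants keep the
  # cohort's all-cause per-cycle death risk (floored at background) rather
  # than background mortality alone, which would double-count the benefit
  q_os_all <- ifelse(s_os[1:n_cyc] > 0, 1 - s_os[2:(n_cyc + 1)] / s_os[1:n_cyc], 1)
  p_rfd <- switch(st$rfd_mortality %||% "os_floor",
                  os_floor = pmax(q_os_all, p_bg),
                  background = p_bg,
                  stop("run_trace: unknown structural$rfd_mortality"))

  sp <- ps$strategies[[strategy]]
  t_hep_days <- sp$n_sessions * sp$session_interval_days
  k_hep <- ceiling(t_hep_days / cyc_d)              # first cycle after treatment end
  p_hep <- sp$hepatectomy_proportion$baseline

  S <- c("PFD", "RFD", "PD", "Death")
  occ <- matrix(0, n_cyc + 1, 4, dimnames = list(NULL, S))
  ent <- matrix(0, n_cyc + 1, 2, dimnames = list(NULL, c("RFD", "PD")))
  pfd <- 1; rfd <- 0; pd_m <- 0; pd_r <- 0; dead <- 0
  occ[1, ] <- c(pfd, rfd, pd_m + pd_r, dead)
  for (k in seq_len(n_cyc)) {
    if (k - 1L == k_hep) {                          # split at start of cycle k_hep
      moved <- p_hep * pfd
      pfd <- pfd - moved
      rfd <- rfd + moved
      ent[k, "RFD"] <- moved
    }
    h_r <- max(h_pd[k], p_bg[k])                    # relapsed PD floor
    new_pd <- pfd * p_to_pd[k]
    new_rec <- rfd * (1 - p_rfd[k]) * p_rec
    dead <- dead + pfd * d_pfd[k] + rfd * p_rfd[k] + pd_m * h_pd[k] + pd_r * h_r
    pd_m <- pd_m * (1 - h_pd[k]) + new_pd
    pd_r <- pd_r * (1 - h_r) + new_rec
    rfd <- rfd * (1 - p_rfd[k]) * (1 - p_rec)
    pfd <- pfd * (1 - q_pfs[k])
    ent[k + 1, "PD"] <- new_pd + new_rec
    occ[k + 1, ] <- c(pfd, rfd, pd_m + pd_r, dead)
  }

  if (occ[n_cyc + 1, "Death"] < 0.999)
    stop("run_trace: horizon too short - Death occupancy ", round(occ[n_cyc + 1, 4], 4),
         " < 0.999 at horizon; increase structural$horizon_years")

  structure(list(strategy = strategy, cycle = 0:n_cyc, time_months = t_m,
                 time_years = t_y, age_years = age, occupancy = occ,
                 entrants = ent, cycle_days = cyc_d, k_hep = k_hep),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  cat(sprintf("Cohort trace, %s: %d cycles of %g days\n", x$strategy, n - 1, x$cycle_days))
  cat(sprintf("  Death occupancy at horizon: %.6f\n", x$occupancy[n, "Death"]))
  cat(sprintf("  undiscounted life expectancy: %.2f years\n", life_years(x, 0)))
  invisible(x)
}

#' Convert a cohort trace to a data.frame
#' @param x a `cohort_trace`.
#' @param ... unused.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = x$cycle, time_months = x$time_months,
             PFD = x$occupancy[, "PFD"], RFD = x$occupancy[, "RFD"],
             PD = x$occupancy[, "PD"], Death = x$occupancy[, "Death"],
             age = x$age_years)
}

#' Discounted life-years of a cohort trace
#'
#' Sum over cycles of alive occupancy times cycle length (years) times the
#' per-cycle discount factor (cycle-start accounting; trapezoidal
#' half-cycle averaging when `half_cycle` is TRUE).
#'
#' @param trace a `cohort_trace`.
#' @param discount_rate annual discount rate.
#' @param half_cycle use the half-cycle (trapezoid) correction.
#' @return discounted life-years.
#' @export
life_years <- function(trace, discount_rate = 0.03, half_cycle = FALSE) {
  alive <- rowSums(trace$occupancy[, c("PFD", "RFD", "PD"), drop = FALSE])
  w <- state_cycle_weights(alive, half_cycle)
  cyc_y <- trace$cycle_days / DAYS_PER_YEAR
  n <- length(w)
  sum(w * cyc_y * discount_factor(trace$time_years[1:n], discount_rate))
}

# per-cycle accrual weights from per-boundary occupancy (length n_cyc)
state_cycle_weights <- function(occ_vec, half_cycle) {
  n <- length(occ_vec) - 1L
  if (half_cycle) (occ_vec[1:n] + occ_vec[2:(n + 1)]) / 2 else occ_vec[1:n]
}
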