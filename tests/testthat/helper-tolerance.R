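# relative-tolerance comparison against an externally reported value
expect_rel <- function(object, expected, tol) {
  act <- quasi_label(rlang::enquo(object))
  rel <- abs(act$val - expected) / abs(expected)
  expect(rel <= tol,
         sprintf("%s = %.6g differs from %.6g by %.1f%% (tolerance %.0f%%)",
                 act$lab, act$val, expected, 100 * rel, 100 * tol))
  invisible(act$val)
}

# independent partitioned-survival oracle: state occupancy read directly off
# the all-cause curves (no Markov chain), for the default hazard-floor
# background mode
partitioned_oracle <- function(ps, strategy) {
  st <- ps$structural
  cyc_d <- st$cycle_length_days
  n_cyc <- ceiling(st$horizon_years * 365.25 / cyc_d)
  t_m <- (0:n_cyc) * cyc_d / 30.4375
  age <- st$start_age_years + (0:n_cyc) * cyc_d / 365.25
  hr_os <- if (strategy == "FOLFOX_HAIC") ps$hr_os$baseline else 1
  hr_pfs <- if (strategy == "FOLFOX_HAIC") ps$hr_pfs$baseline else 1
  th <- ps$os_tace$params
  pf <- ps$pfs_tace$params
  s_os <- (1 / (1 + th[["theta"]] * t_m^th[["kappa"]]))^hr_os
  s_pfs <- pmin((1 - pnorm((log(pmax(t_m, 1e-300)) - pf[["mu"]]) / pf[["sigma"]]))^hr_pfs, s_os)
  s_pfs[1] <- 1
  p_bg <- annual_to_cycle_prob(annual_mortality(ps$life_table, age[1:n_cyc]), cyc_d)
  floorize <- function(s) {
    q <- ifelse(s[1:n_cyc] > 0, 1 - s[-1] / s[1:n_cyc], 1)
    cumprod(c(1, 1 - pmax(q, p_bg)))
  }
  s_os <- floorize(s_os)
  s_pfs <- pmin(floorize(s_pfs), s_os)
  cbind(PFD = s_pfs, RFD = 0, PD = s_os - s_pfs, Death = 1 - s_os)
}

# life-table survival evaluated independently from piecewise-constant hazards
bg_survival_oracle <- function(lt, start_age, t_years) {
  haz <- -log(1 - lt$annual_prob)
  upper <- ifelse(is.infinite(lt$age_high), Inf, lt$age_high + 1)
  vapply(t_years, function(ty) {
    H <- 0
    for (i in seq_len(nrow(lt))) {
      a0 <- max(lt$age_low[i] - start_age, 0)
      a1 <- min(upper[i] - start_age, ty)
      if (a1 > a0) H <- H + haz[i] * (a1 - a0)
    }
    exp(-H)
  }, numeric(1))
}
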