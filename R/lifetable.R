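#' Age-banded life table
#'
#' Builds a background-mortality life table from age bands and annual death
#' probabilities. Bands must be contiguous from age 0; the terminal band is
#' open-ended (any age at or beyond its lower bound resolves to it).
#'
#' @param age_low,age_high integer band bounds in years (inclusive low,
#'   inclusive high; the terminal band's `age_high` may be `Inf`).
#' @param annual_prob annual probability of death in each band, in `[0, 1]`.
#' @return data.frame of class `life_table`.
#' @export
life_table <- function(age_low, age_high, annual_prob) {
  stopifnot(length(age_low) == length(age_high),
            length(age_low) == length(annual_prob))
  if (age_low[1] != 0) stop("life_table: first band must start at age 0")
  if (any(annual_prob < 0 | annual_prob > 1)) stop("life_table: probabilities must be in [0, 1]")
  n <- length(age_low)
  if (n > 1 && any(age_low[-1] != age_high[-n] + 1))
    stop("life_table: bands must be contiguous and non-overlapping")
  structure(data.frame(age_low = age_low, age_high = age_high, annual_prob = annual_prob),
            class = c("life_table", "data.frame"))
}

lt_band_index <- function(lt, age) {
  idx <- findInterval(age, lt$age_low)
  idx[idx < 1L] <- 1L
  idx
}

#' Annual background mortality at a given age
#'
#' Looks up the life-table band containing `age`. Ages beyond the terminal
#' band take the terminal band's value.
#' @param lt a [life_table].
#' @param age age in years (vectorized), `>= 0`.
#' @export
annual_mortality <- function(lt, age) {
  if (any(age < 0)) stop("annual_mortality: age must be >= 0")
  lt$annual_prob[lt_band_index(lt, age)]
}

#' Per-cycle background mortality probability
#'
#' Converts the annual band probability at `age` to a cycle of
#' `cycle_days` days via [annual_to_cycle_prob()].
#' @inheritParams annual_mortality
#' @param cycle_days cycle length in days.
#' @export
background_mortality <- function(lt, age, cycle_days) {
  annual_to_cycle_prob(annual_mortality(lt, age), cycle_days)
}

#' Background survival function from a starting age
#'
#' Survival of a disease-free person under the life table alone, from
#' `start_age`, with a piecewise-constant hazard within each band
#' (\eqn{\lambda = -\log(1 - p)} per year; a band with annual probability 1
#' is absorbing). Returns a function of time in months.
#'
#' @param lt a [life_table].
#' @param start_age starting age in years.
#' @return function mapping time (months) to survival probability.
#' @export
lifetable_survival <- function(lt, start_age) {
  haz <- -log(1 - lt$annual_prob)          # per-year; Inf where prob == 1
  breaks <- pmax(lt$age_low - start_age, 0) # years after start when each band begins
  upper <- c(breaks[-1], Inf)
  force(haz)
  function(t_months) {
    t_years <- t_months * DAYS_PER_MONTH / DAYS_PER_YEAR
    H <- vapply(t_years, function(ty) {
      dur <- pmin(ty, upper) - pmin(ty, breaks)
      sum(ifelse(dur > 0, haz * dur, 0))
    }, numeric(1))
    exp(-H)
  }
}

#' Blend disease-specific survival with background mortality
#'
#' All-cause survival as the product of independent risks:
#' \eqn{S_{all}(t) = S_{disease}(t) \times S_{bg}(t)}.
#'
#' @param S_disease disease-specific survival function (time in months).
#' @param lt a [life_table].
#' @param start_age cohort starting age in years.
#' @return all-cause survival function of time in months.
#' @export
blend_background <- function(S_disease, lt, start_age) {
  S_bg <- lifetable_survival(lt, start_age)
  function(t) S_disease(t) * S_bg(t)
}
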