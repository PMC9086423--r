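os_tace:
  family: log_logistic
  params:
    theta: 0.00272126
    kappa: 2.184792
pfs_tace:
  family: lognormal
  params:
    mu: 1.682471
    sigma: 1.119812
hr_os:
  baseline: 0.58
  low: 0.45
  high: 0.75
  distribution: lognormal
hr_pfs:
  baseline: 0.57
  low: 0.45
  high: 0.72
  distribution: lognormal
recurrence_prob:
  baseline: 0.19
  low: 0.15
  high: 0.2
  distribution: beta
utilities:
  PFD:
    baseline: 0.76
    low: 0.61
    high: 0.91
    distribution: beta
  RFD:
    baseline: 0.76
    low: 0.61
    high: 0.91
    distribution: beta
  PD:
    baseline: 0.68
    low: 0.54
    high: 0.82
    distribution: beta
ae_costs:
  elevated_alt_ast:
    baseline: 43.0
    low: 35.0
    high: 52.0
    distribution: gamma
  vomiting:
    baseline: 49.0
    low: 39.0
    high: 59.0
    distribution: gamma
ae_disutilities:
  elevated_alt_ast:
    baseline: 0.0
    low: 0.0
    high: 0.0
    distribution: fixed
  vomiting:
    baseline: 0.05
    low: 0.04
    high: 0.06
    distribution: beta
shared_costs:
  hepatectomy:
    baseline: 9022.0
    low: 7218.0
    high: 10827.0
    distribution: gamma
  hospitalization_per_cycle:
    baseline: 384.0
    low: 307.0
    high: 460.0
    distribution: gamma
  bsc_per_cycle:
    baseline: 363.0
    low: 291.0
    high: 436.0
    distribution: gamma
discount_rate_annual:
  baseline: 0.03
  low: 0.01
  high: 0.05
  distribution: uniform
life_table:
  age_low:
  - 0.0
  - 1.0
  - 5.0
  - 10.0
  - 15.0
  - 20.0
  - 25.0
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  age_high:
  - 0.0
  - 4.0
  - 9.0
  - 14.0
  - 19.0
  - 24.0
  - 29.0
  - 34.0
  - 39.0
  - 44.0
  - 49.0
  - 54.0
  - 59.0
  - 64.0
  - 69.0
  - 74.0
  - 79.0
  - 84.0
  - -1.0
  annual_prob:
  - 0.006763658
  - 0.001144414
  - 0.000924507
  - 0.000969999
  - 0.00179698
  - 0.002810805
  - 0.003052746
  - 0.004239707
  - 0.006187994
  - 0.009315495
  - 0.012327216
  - 0.01956602
  - 0.030500498
  - 0.048778564
  - 0.078138957
  - 0.137236768
  - 0.221445846
  - 0.371374039
  - 1.0
strategies:
  FOLFOX_HAIC:
    name: FOLFOX_HAIC
    per_session_costs:
      oxaliplatin:
        baseline: 426.0
        low: 340.0
        high: 511.0
        distribution: gamma
      fluorouracil:
        baseline: 524.0
        low: 419.0
        high: 629.0
        distribution: gamma
      leucovorin:
        baseline: 24.0
        low: 19.0
        high: 29.0
        distribution: gamma
      HAIC:
        baseline: 1850.0
        low: 1480.0
        high: 2220.0
        distribution: gamma
    n_sessions: 3.6
    session_interval_days: 21.0
    hospitalize_during_treatment: yes
    hepatectomy_proportion:
      baseline: 0.24
      low: 0.19
      high: 0.29
      distribution: beta
    ae_incidence:
      elevated_alt:
        baseline: 0.08
        low: 0.06
        high: 0.1
        distribution: beta
      elevated_ast:
        baseline: 0.18
        low: 0.14
        high: 0.22
        distribution: beta
      vomiting:
        baseline: 0.06
        low: 0.05
        high: 0.07
        distribution: beta
    subsequent_mix:
      BSC:
        baseline: 0.95
        low: 0.76
        high: 1.14
        distribution: beta
      crossover:
        baseline: 0.05
        low: 0.04
        high: 0.06
        distribution: beta
  TACE:
    name: TACE
    per_session_costs:
      TACE:
        baseline: 1929.0
        low: 1543.0
        high: 2315.0
        distribution: gamma
    n_sessions: 2.0
    session_interval_days: 42.0
    hospitalize_during_treatment: no
    hepatectomy_proportion:
      baseline: 0.12
      low: 0.1
      high: 0.14
      distribution: beta
    ae_incidence:
      elevated_alt:
        baseline: 0.19
        low: 0.15
        high: 0.23
        distribution: beta
      elevated_ast:
        baseline: 0.29
        low: 0.23
        high: 0.35
        distribution: beta
      vomiting:
        baseline: 0.05
        low: 0.04
        high: 0.06
        distribution: beta
    subsequent_mix:
      BSC:
        baseline: 0.87
        low: 0.7
        high: 1.04
        distribution: beta
      crossover:
        baseline: 0.13
        low: 0.1
        high: 0.16
        distribution: beta
structural:
  cycle_length_days: 21.0
  start_age_years: 55.0
  horizon_years: 35.0
  wtp_per_qaly: 30552.0
  half_cycle_correction: no
  background_mode: floor
  recurrence_basis: five_year
  rfd_mortality: os_floor
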