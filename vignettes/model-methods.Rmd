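---
title: "A Markov cohort model of FOLFOX-HAIC versus TACE in large unresectable HCC: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haiccea)
```

## The decision problem

Transarterial chemoembolization (TACE) is the standard first-line therapy
for intermediate-stage hepatocellular carcinoma, but its response rate in
*large* unresectable tumours is poor. Hepatic arterial infusion
chemotherapy with infusional fluorouracil, leucovorin and oxaliplatin
(FOLFOX-HAIC) improves survival in this population at a higher drug and
administration cost. `haiccea` implements a cohort state-transition
(Markov) model that weighs that survival gain against the cost difference
from the Chinese health-system perspective, in discounted US dollars and
quality-adjusted life-years (QALYs), and judges cost-effectiveness against
a willingness-to-pay (WTP) threshold of $30,552/QALY (three times China's
2020 per-capita GDP).

## Model structure

Patients enter at age 55 with large unresectable HCC and receive either
FOLFOX-HAIC (mean 3.6 sessions, one every 21 days) or TACE (mean 2
sessions, one every 42 days). Four health states are tracked on 21-day
cycles:

* **PFD** — progression-free disease on or after first-line treatment;
* **RFD** — recurrence-free disease after conversion hepatectomy;
* **PD** — progressed disease, managed with best supportive care (BSC) or
  crossover to the other arm's regimen;
* **Death**, absorbing.

At the first cycle boundary after the mean treatment course (about 11
weeks in both arms), 24% (FOLFOX-HAIC) or 12% (TACE) of the still
progression-free cohort undergoes hepatectomy and moves to RFD; RFD
carries the PFD utility and a constant recurrence hazard back to PD.

### Survival inputs

TACE overall survival (OS) follows a log-logistic model
$S(t) = 1/(1+\theta t^\kappa)$ with $\theta = 0.00272126$,
$\kappa = 2.184792$ (median 14.9 months), and TACE progression-free
survival (PFS) a lognormal model
$S(t) = 1-\Phi((\log t-\mu)/\sigma)$ with $\mu = 1.682471$,
$\sigma = 1.119812$ (median 5.4 months); time is in months of 30.4375
days. FOLFOX-HAIC curves apply trial hazard ratios (OS 0.58, PFS 0.57)
as $S(t)^{hr}$ under proportional hazards. PFS is capped at OS pointwise,
since independently fitted curves can cross in the extrapolated tail.

### Background mortality

Age-banded annual death probabilities for the general Chinese population
(terminal 85+ band absorbing) enter, by default, as a per-cycle hazard
floor: the cohort's per-cycle death probability is
$\max(q_{disease}, q_{background})$. The floor formulation treats the
extrapolated trial curve as the all-cause mortality of trial-like
patients, letting the life table take over only where the fitted curve's
hazard falls below plausible all-cause levels (the log-logistic hazard
declines in the tail, so without the floor a fraction of the cohort would
outlive any human lifespan). A multiplicative independent-competing-risk
blend ($S_{all} = S_{disease}\times S_{bg}$) is available as
`structural$background_mode = "multiplicative"`; it yields a slightly
lower ICER (about $6,900 versus $9,800 per QALY at baseline), and the
cost-effectiveness conclusion is unchanged under either mode.

### From curves to transition probabilities

Writing $S^{OS}_k$, $S^{PFS}_k$ for the all-cause curves at cycle
boundary $k$, partitioned-survival occupancy would be
$PFD_k = S^{PFS}_k$, $PD_k = S^{OS}_k - S^{PFS}_k$,
$Death_k = 1 - S^{OS}_k$. The engine converts these into per-person,
per-cycle transition probabilities: PFD is left at the conditional rate
$1 - S^{PFS}_{k+1}/S^{PFS}_k$; deaths in the cycle
($S^{OS}_k - S^{OS}_{k+1}$) are attributed first to PFD occupants at the
background rate, the remainder to PD occupants (their exit hazard
$h^{PD}_k$), with any excess the PD pool cannot absorb (early cycles,
where PD is still nearly empty) drawn from PFD directly. The
decomposition is exact, so with the hepatectomy proportion set to zero
the chain reproduces partitioned occupancy to numerical precision — a
property the test suite asserts at $10^{-9}$. Occupancy rows are never
renormalized; conservation holds by construction.

### The hepatectomy branch

Two aspects of the post-hepatectomy course are unspecified in the source
material and were resolved as follows:

* **RFD mortality** (`structural$rfd_mortality`). The trial OS curves
  already contain the 24%/12% of patients who underwent hepatectomy, so
  granting RFD occupants background-only mortality would count the
  surgical survival benefit twice — and drives both arms' QALYs some
  20–25% above the published results. The default `"os_floor"` therefore
  keeps RFD occupants at the cohort's all-cause OS-based per-cycle death
  risk, floored at background mortality; hepatectomy then matters through
  the utility and cost pathways. `"background"` (hepatectomy as cure)
  remains available.
* **Recurrence** (`structural$recurrence_basis`). The recurrence
  probability 0.19 (range 0.15–0.20) is converted to a constant hazard on
  a 5-year cumulative basis by default,
  $r = -\log(1-0.19)/5$ per year; an annual basis is available, as the
  printed parameter table does not state a time unit. Recurrent patients
  enter PD and exit at the model's PD death hazard, floored at background
  mortality.

### Costs and utilities

All costs are USD. Per-session first-line costs (oxaliplatin 426,
fluorouracil 524, leucovorin 24, HAIC administration 1,850; TACE 1,929)
are charged on each arm's calendar schedule, weighted by PFD occupancy at
the session time; a fractional mean session count weights the final
session (3.6 sessions → weights 1, 1, 1, 0.6). Hospitalization
($384/cycle) is charged during first-line treatment cycles of FOLFOX-HAIC
only: the 24-hour infusions require admission and the charge is sourced
alongside the HAIC regimen costs, whereas the TACE procedure cost comes
from a TACE-specific costing study and is treated as
admission-inclusive (`hospitalize_during_treatment` per strategy).
Hepatectomy ($9,022) is a one-off at RFD entry. PD occupants accrue BSC
($363/cycle) on the BSC share (95%/87%) and, on the crossover share
(5%/13%), the other regimen's full course priced at PD entry with each
session discounted at its own calendar time — attrition during the 6–11
week crossover course is ignored, a small overstatement of crossover
cost. Grade ≥3 adverse events (elevated ALT, elevated AST, vomiting) are
one-off at model entry: cost = incidence × unit cost, and a QALY
decrement of incidence × disutility × one cycle's duration (only vomiting
has a nonzero disutility, 0.05).

Utilities are 0.76 for PFD and RFD and 0.68 for PD. Everything is
discounted at 3%/year, $(1.03)^{-t}$, evaluated at cycle start; a
half-cycle (trapezoid) correction is available
(`structural$half_cycle_correction`) and shifts results by well under 1%
at this cycle length.

## Sensitivity and subgroup analysis

**One-way (tornado).** Every uncertain parameter is set to its low and
high bound in turn (95% CIs where published, ±20% of baseline otherwise,
clamped to the distribution's support) and the ICER recomputed; rows are
sorted by spread. At baseline the two hazard ratios dominate, and no
single-parameter variation pushes the ICER above the WTP threshold.

**Probabilistic (PSA).** 10,000 Monte-Carlo draws sample every parameter
independently: gamma for costs and beta for probabilities/utilities by
method of moments with mean = baseline and SD = (high − low)/3.92 (the
ranges are 95%-CI-like); lognormal hazard ratios matching the CI
endpoints on the log scale; uniform for the discount rate. Beta draws
whose moment match is infeasible fall back to a uniform on the clamped
range; sampled proportions are clamped to [0, 1]; the BSC/crossover mix
is renormalized to sum to 1; survival-curve shape parameters are held
fixed (no distribution is published for them), which may make the
acceptability probability slightly optimistic. The cost-effectiveness
acceptability curve is reported on a 200-point WTP grid from 0 to three
times the threshold, with ties (NMB = 0) counted as cost-effective.

**Subgroups.** The 16 trial subgroups replace the pooled hazard ratios
with subgroup-specific values applied to the pooled TACE baseline curves.
This is an approximation: a full subgroup-survival reconstruction would
also adjust the baseline curve per subgroup, which cannot be recovered
from the published data. Deterministic subgroup ICERs track the published
ones closely (15 of 16 within about 10%), and the qualitative pattern —
smallest ICER for age ≤50, largest for hepatitis-B-negative patients,
where FOLFOX-HAIC is not cost-effective — is reproduced.

## Synthetic patient-level data

`simulate_ipd()` draws event times from the model curves by inverse
transform (closed-form inverses for both families, including the
$S^{hr}$ transform) with administrative censoring at a trial-like 24
months, and `fit_parametric()` refits by maximum likelihood
(log-scale parameterization, observed-information standard errors). This
closes the loop the published analysis performed on reconstructed
Kaplan–Meier data: the test suite verifies that refitting n = 2,000
simulated patients recovers the published curve parameters within 3
standard errors, that the sampler's empirical CDF matches the closed form
(Kolmogorov–Smirnov distance < 0.01 at n = 10^5), and that estimates
agree with an independent location-scale implementation
(`survival::survreg`). The generator emulates administrative censoring
only — no dropout, no interval censoring, and no digitization error of
the kind real curve reconstruction would carry — so recovery tests
demonstrate correctness of the sampling/fitting machinery, not robustness
to real-data artefacts.

## Numerical choices

* Cycle length 21 days; 1 month = 30.4375 days; discounting per cycle
  start.
* Horizon 35 years (to age 90). The absorbing 85+ life-table band then
  guarantees full cohort absorption for any hazard-ratio draw a subgroup
  PSA can produce; the trace constructor errors if Death occupancy at the
  horizon falls below 0.999. A 30-year horizon ends exactly at the 85+
  band boundary and can leave around 1% of the cohort alive under
  favourable draws.
* The base case runs 609 cycles per arm in a few hundredths of a second;
  the 10,000-draw PSA takes about a minute on one core; the full test
  suite, including a complete PSA and the recovery checks, a few minutes.
* Fixed seeds everywhere: every stochastic entry point takes a `seed`
  argument, and the baseline (deterministic) results are invariant to PSA
  seeds.

## Limitations

The model inherits the published analysis's limitations: extrapolation
well beyond trial follow-up from two-parameter curves; utilities shared
across arms; crossover modeled as a cost/utility weighting of PD rather
than a survival modifier (the trial OS already reflects post-progression
care); AE burden applied once at entry. The structural choices above
(background-mortality mode, RFD mortality, recurrence basis,
hospitalization scope) are exactly the places where the source is silent;
all are exposed in the configuration, and the headline conclusion — an
ICER well below $30,552/QALY, robust in one-way and probabilistic
analysis, except among hepatitis-B-negative patients — holds across every
combination.
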