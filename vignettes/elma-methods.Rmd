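---
title: "Expected labor market affiliation: model, estimator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected labor market affiliation: model, estimator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Work-related stress is associated with sickness absence, unemployment and
early labor-market exit, but most analyses look at one outcome at a time.
This package estimates the *expected labor market affiliation* (ELMA): the
expected number of days an employee spends in each of seven mutually
exclusive labor-market states over a fixed two-year (730-day) horizon, as a
function of a work-stress exposure, and converts shortfalls in expected
workdays into monetary absenteeism costs.

The state space has four recurrent states — `work`, `sickness_absence`,
`unemployment`, `temporary_out` — and three absorbing states —
`retirement`, `disability_pension`, `death`. Every recurrent state has an
arrow to each of the six other states, giving 24 permitted transitions.
The exposure is the count (0–3) of three dichotomous work-stress
indicators: self-perceived work stress, a four-item perceived-stress scale
restricted to work, and job strain (high quantitative demands with low
influence). Employees with zero indicators form the reference group.

Formally, let $X(t)$ be the state occupied at day $t$ and
$\alpha_{hj}(t)$ the transition intensity from $h$ to $j$. For exposure
level $\ell$ the model is a proportional-hazards multi-state model on a
common (clock-forward) time scale,
$\alpha_{hj}(t \mid \ell) = \alpha^0_{hj}(t)\,e^{\beta_{hj,\ell}}$,
with the Markov assumption that intensities depend on the past only
through the current state.

## The estimator

1. **Event history.** Register-style payment records are resolved to one
   state per day: absorbing states take priority over recurrent payments
   (death over disability pension over retirement), and among simultaneous
   recurrent payments the one with most recorded hours per day wins. Days
   without any payment inherit the preceding state, since the registers
   record no leisure time; this also carries vacation days. Episodes are
   half-open integer-day intervals `[start, end)` that tile the follow-up.
   Follow-up is censored at the first of: the 730-day horizon, the day the
   person turns 65, the start of the person's next follow-up, or a new
   employer id.

2. **Risk sets.** Each recurrent episode in state $h$ contributes one
   record per permitted destination $j$, with an event indicator only for
   the destination actually entered. Time is days since follow-up start,
   shared across repeated visits to $h$ — this realizes the Markov
   assumption; the alternative sojourn-time scale would give a semi-Markov
   model, which is out of scope.

3. **Transition hazards.** For each of the 24 arrows, a weighted Cox
   partial likelihood with Breslow tie handling (ties are unavoidable on a
   day grid) estimates $\beta_{hj}$ for the three exposure indicators, and
   the Breslow estimator at the reference level gives the baseline
   cumulative-hazard increments
   $d\hat A^0_{hj}(t) = d_{hj}(t) / \sum_{i \in R_h(t)} w_i e^{\hat\beta' z_i}$.

4. **Transition probabilities.** At every pooled event day the increment
   matrix $d\hat A(t)$ (off-diagonals scaled by $e^{\hat\beta_{hj,\ell}}$,
   diagonal minus the row sum) enters the product integral
   $\hat P(0,t) = \prod_{t_m \le t}\bigl(I + d\hat A(t_m)\bigr)$ — the
   empirical solution of the Chapman–Kolmogorov equations, i.e. the
   Aalen–Johansen estimator. If an off-diagonal row sum exceeds 1 (possible
   with heavy ties) the row is rescaled to keep $\hat P$ stochastic; this
   is logged and in practice touches at most a handful of days.

5. **Durations.** With start distribution $\pi$ (the observed start-state
   frequencies of the stratum-by-exposure cell), the state-occupation
   probabilities $p_k(t) = \sum_h \pi_h \hat P_{hk}(0,t)$ are piecewise
   constant, so the expected days
   $\hat E_k = \int_0^{730} p_k(t)\,dt$ are an exact step-function sum.
   Durations over the seven states add up to 730 by construction.
   Differences $\Delta_k(\ell) = \hat E_k(\ell) - \hat E_k(0)$ sum to zero
   across states. Everything is stratified by the six sex-by-age subsamples
   (18–34, 35–49, 50–64).

6. **The crude comparator** is the per-cell mean of observed days per
   state (sum of days over employees divided by the head count). It agrees
   with ELMA on uncensored homogeneous data but is biased toward shorter
   durations whenever observation ends early, because it ignores the
   censoring structure.

## Confounder adjustment by weighting

Covariates never enter the Cox linear predictor; they act through weights,
so the exposure contrasts stay marginal. Per stratum, a multinomial
logistic model of the exposure count on the nine baseline covariates (BMI,
smoking, alcohol, physical activity, disease treatment, working-time
arrangement, sector, education, number of survey waves; explicit
"not available" levels) yields propensities, and the stabilized weight is
the marginal level frequency over the propensity of the observed level.
Propensities are floored at 0.001 (affected records are counted and
warned about; under the default generator fewer than 1% are touched). The
analysis weight is the IPW multiplied by the register sampling weight.
Weights are computed once at follow-up start: only education may change
during follow-up, and no reweighting rule over time is defined, so
time-varying covariate values affect coding only. The model form and
stabilization are this package's choices; standard IPW practice was
followed where the procedure was otherwise unspecified.

## Resampling confidence intervals

Intervals come from 1000 (by default) normally distributed resamples of
the fitted model, with durations recomputed per draw and empirical
2.5/97.5 percentiles reported. Two design questions were genuinely open
and resolved as follows:

* **Baseline uncertainty is included.** Reference-level durations depend
  only on the baseline hazards; perturbing coefficients alone would give
  the reference rows zero-width intervals. Each draw therefore rebuilds
  every baseline from perturbed weighted event counts over the
  coefficient-dependent Breslow denominator
  $\sum_\ell e^{\beta^*_\ell} D_{\ell}(t)$, which also carries the
  correlation between $\hat\beta$ and $\hat A^0$ into the intervals.
* **Event-count draws are gamma, coefficients normal.** Daily event
  counts are small (often 1–3), so zero-truncated normal draws lose
  15–35% of their variance exactly where it matters. A gamma draw with
  mean $d$ and variance $\sum w_i^2$ (the weighted Poisson-type variance)
  keeps both moments without truncation. Coefficient vectors are drawn
  from their asymptotic normal, independently across transitions.
  Coefficients that hit the $\pm 10$ cap (monotone likelihood) or belong
  to levels absent from the data are flagged unidentified and held fixed —
  their reported covariance is meaningless and resampling it explodes a
  near-zero hazard by $e^{10}$.
* **Start distributions** are redrawn as multinomial frequencies at the
  cell sample size, since the observed $\hat\pi$ is itself an estimate.

A calibration experiment (`ci_coverage_experiment()`) simulating 100–200
cohorts of 1000 persons with 200 resamples each puts the coverage of the
95% intervals at roughly 0.93–0.99 for expected work and sickness-absence
days at exposure levels 0 and 1.

## Cost conversion

Costs follow the human-capital approach: lost work time is valued at the
individual gross wage. Work payments are standardized to hourly rates
using the Danish norm of 7.4 working hours per day (37-hour week) and
truncated to 6.72–268.63 EUR/hour (DKK 50–2000 at the fixed implied rate
of 7.44 DKK/EUR; the rate is implied by the pair of published bounds).
Missing rates are imputed by a log-linear regression on sex, age group,
education, sector and industry group, then everything is indexed to 2022
prices with a sex- and age-specific CPI table supplied via configuration
(the national series values are not published; a deterministic synthetic
series ships as the default).

A two-year duration difference $\Delta_k$ converts to an annual cost at
rate $r$ as $C_k = r \times 7.4 \times \Delta_k / 2$ for sickness absence,
unemployment and temporary out, and
$C_A = r \times 7.4 \times (-\Delta_{work})/2$ for work absenteeism — the
division by two annualizes the two-year horizon; negative values are
savings. Each exposed individual's own wage is used and survey-weighted
averages and totals are formed per stratum-by-level cell; "Total" rows per
sex average the exposed cells with exposed-count weights. The headline
table is restricted to full-time employees (at least 95% of the 37-hour
norm), with a part-time-inclusive variant behind a flag. The component
identity $C_A = C_{sick} + C_{unemp} + C_{temp} + r \cdot 3.7 \cdot
\Delta_{absorbing}$ holds exactly because the deltas sum to zero.
Coverage is the weighted sample size over a configured national workforce
count. Reduction scenarios re-assign a fraction $f$ of exposed follow-ups
(drawn as a seeded permutation within each level, so scenarios are nested
and monotone in $f$) to the reference level and recompute the totals.

## The synthetic registry

No public microdata exist for this design — the source registers are
accessible only through a national statistics office — so the package
ships a generator that emulates their structure with known ground truth:

* **Trajectories** are exact samples of a continuous-time Markov chain
  with per-stratum, per-exposure-level intensity matrices, discretized to
  whole days by labelling each day with the state occupied at its start
  (registers are date-based; ties within a day resolve to the last state
  before the day boundary). The closed-form oracle
  $E^* = \pi^{\top}\!\int_0^{T} e^{Qt}\,dt$ is computed via the augmented
  matrix exponential
  $\exp\!\bigl(\begin{smallmatrix} Q & I \\ 0 & 0\end{smallmatrix}\bigr)T$
  and cross-checked against dense ODE integration in the tests.
* **Calibration.** Reference-group intensities are set so occupancies are
  of realistic register magnitude (about 700 of 730 days in work for men
  35–49, with roughly 16 sickness-absence days, rare unemployment and
  temporary-out spells, and infrequent absorbing events; women 18–34 get a
  large temporary-out occupancy reflecting parental leave, and the oldest
  strata a substantial retirement flow). Exact replication of any
  published table is explicitly not a goal. Exposure multiplies the
  work-to-sickness intensity by 1.5/1.75/2.0 at 1/2/3 indicators and the
  work-to-unemployment intensity by 1.2/1.4/1.6.
* **Indicator counts** are drawn from per-stratum distributions matching
  published survey margins (about 63–74% with zero indicators and 2–5%
  with all three). Drawing the three indicators independently cannot
  reproduce both the per-indicator margins (11–23%) and the share of
  triple-positives, so the count is drawn first and the positive
  indicators are then picked proportionally to their margins; an
  `independent` mode exists for sensitivity.
* **Wages and weights** are log-normal (stratum-specific medians of about
  20–31 EUR/h, log-sd 0.35, chosen so average annual wages are of the
  order implied by published per-employee percentages), with a configurable
  fraction of missing wage observations; survey weights are calibrated to
  sum to a configurable represented population (default 1,230,754) and
  register weights scatter around one. An optional confounding switch
  makes smoking raise both the exposure odds and the work-to-sickness
  intensity, for testing the weighting stage.

What the generator does **not** emulate: duration-dependent (semi-Markov)
hazards, seasonality and calendar-time trends, measurement error in the
stress indicators, informative censoring, clustered employers, or the
heavy-tailed empirical wage distribution. Passing tests therefore
demonstrate that the estimator recovers a known Markov truth and that the
pipeline's accounting is exact — not that real register data satisfy the
model's assumptions.

## Numerical choices and degenerate inputs

* Half-open integer-day episodes; day ties keep the state occupied at the
  start of the day.
* Breslow ties and Breslow baseline throughout (tie handling is otherwise
  unspecified; Efron would differ negligibly at these risk-set sizes).
* Log-hazard-ratio cap $\pm 10$ for monotone likelihood, with the
  unidentified flag described above.
* Product-integral rows exceeding unit mass are rescaled (warning);
  a row that cannot be repaired is a hard error.
* Zero-event transitions degenerate to a zero hazard with a warning —
  routine for rare absorbing arrows in small cells.
* Empty stratum-by-exposure cells fall back to the stratum-wide start
  distribution for $\pi$ and are reported as missing in crude tables.
* The matrix-exponential oracle validates its generator (nonnegative
  off-diagonals, zero row sums, absorbing rows, no forbidden arrows).
* Propensity floor 0.001; imputation falls back to the sex-age stratum
  geometric mean for unseen covariate levels.

## Problem sizes

The validation suite uses cohorts of 5000 persons for oracle-equivalence
and parameter-recovery checks (Monte-Carlo standard errors of rare-state
occupancies are a few percent at that size, so per-state tolerances take
the larger of 1% of the oracle value and three Monte-Carlo standard
errors), 200 replicates of 1000 persons with 200 resamples for interval
calibration, and a 10,000-person six-stratum cohort for the worked
analysis under `analysis/`. These sizes were chosen so each stage gives
stable estimates while the whole workflow remains comfortable to re-run on
a laptop.

## Known limitations

* The Markov, clock-forward assumption ignores sojourn-time dependence
  (e.g. long sickness spells lowering the return rate).
* Exposure is fixed at follow-up start; within-follow-up changes in
  work stress are not modeled.
* Coefficient draws are independent across transitions; cross-transition
  covariance of the estimates is not captured (it is zero asymptotically
  for distinct counting processes under the model, but not in finite
  samples).
* The cost layer prices lost work time only — no healthcare, medication,
  presenteeism or quality-of-life components — and inherits the register
  convention that simultaneous payments resolve to a single state, which
  slightly understates working time.
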