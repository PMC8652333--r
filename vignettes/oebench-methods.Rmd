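---
title: "Methods: benchmarking observed-vs-expected background rate comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking observed-vs-expected background rate comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Safety surveillance after a vaccination campaign often starts from an
observed-vs-expected (O/E) comparison: count adverse events in a
time-at-risk (TAR) window after vaccination, project the number that would
have been *expected* from historical ("background") rates in the same
population, and flag outcomes occurring more often than expected. The
design is attractive — it needs no concurrent comparator and can run on
accumulating data month by month — but it is vulnerable to every way the
historical population and period differ from the vaccinated ones:
age-sex composition, healthcare-seeking behaviour, seasonality and secular
trends, and event-recording patterns around healthcare contacts.

`oebench` provides a fully synthetic, end-to-end benchmark of this design.
It generates OMOP-style event tables with switchable bias mechanisms, runs
the O/E analysis under four background-rate designs, synthesizes positive
control outcomes at known effect sizes, applies empirical calibration with
a leave-one-out systematic error model, and scores everything with the
standard method-evaluation metrics (type 1/2 error, AUC, CI coverage,
precision, MSE, timeliness). Because the ground truth of every control is
known by construction, each metric is exactly interpretable.

## The simulated world

Calendar time is integer days with day 0 the start of the vaccination
campaign. The surveillance window is `[0, 30 * n_months)`; accrual months
are 30-day blocks, which keeps the calendar dialect-free. The historical
window is the mirror of the surveillance window one year earlier
(`surveillance - 365` days), matching the convention of taking background
rates from the same months of the preceding year. Every person holds one
observation period spanning both windows; enrollment churn is deliberately
not modelled (it is second-order for the estimators under study and would
add a censoring model the benchmark does not need).

Per person, the tables are:

* **persons** — sex drawn from `female_fraction` (default 0.511, a
  commercial-claims-like share; a Medicaid-like profile uses 0.5623), age
  at day 0 drawn from ten-year band weights, uniform within band.
* **visits** — a homogeneous outpatient-visit process at `visit_rate`
  (default 3/person-year, a typical outpatient contact rate).
* **exposures** — first doses only. A *rapid* uptake curve places 60% of
  doses in the peak month and 25% in the next (≥ 80% in months 1–2,
  emulating pandemic-influenza-like campaigns); a *slow* curve spreads
  doses uniformly over the surveillance months (HPV- or zoster-like).
  Each dose also records a visit on the dose day — vaccination is a
  healthcare contact, and this coupling is what lets visit-proximity
  recording bias act on the post-vaccination window.
* **outcomes** — recurrent events from a thinned inhomogeneous Poisson
  process with per-day hazard

  `base_rate/365.25 × age_mult(band) × sex_mult × (1 + A sin(2π day/360)) × (1+s)^(day/365.25)`

  (seasonal amplitude `A`, secular slope `s` per year).

Three bias knobs, all neutral by default:

* `age_confounding_strength` — vaccination propensity ∝
  `exp(strength × age_band)`; with age-varying outcome rates this is
  confounding by indication.
* `healthy_vaccinee_shift` — multiplies the outcome hazard over *all*
  person-time of (eventually) vaccinated persons; being a person-level
  attribute it also shifts their historical rates, so with coverage `c`
  the induced O/E bias is `shift / ((1-c) + c·shift)`, identical on the
  log scale for every outcome — exactly the constant-bias world empirical
  calibration assumes.
* `visit_capture_boost` — multiplies the *recording* hazard within
  `visit_capture_days` (default 30) after any visit, emulating events that
  only enter the data when the patient is in contact with care.

Each table draws from its own RNG stream derived from the master seed by a
fixed offset, so regenerating one table never disturbs the others and
identical configurations are bit-for-bit reproducible.

What the generator does **not** emulate: enrollment churn and partial
observation, code-level phenotype error, multi-dose schedules, regional or
database heterogeneity, and outcome-dependent care seeking. A green test
therefore establishes that the *estimators and calibration machinery*
behave as claimed in a world whose biases are exactly the three mechanisms
above — not that any particular real database satisfies those assumptions.

## The four background-rate designs

Crossing two flags gives the four designs evaluated:

* **unadjusted** — cohort-style background: each person's full time in the
  historical interval, first event per person; a single marginal rate.
* **age-sex adjusted** — the same, stratified by ten-year age band and sex;
  the expected count is `E = Σ_s rate_s × PT_s` over the observed
  (post-vaccination) person-time strata.
* **visit-anchored** — background person-time is the TAR after one
  outpatient visit drawn uniformly at random per person from their visits
  in the historical interval; persons without such a visit contribute
  nothing. Anchoring reproduces the healthcare-contact context in which
  vaccination happens, so visit-proximity recording inflation cancels
  between numerator and denominator.
* **anchored + adjusted** — both.

The observed side is identical across designs: index at the vaccination
day, first event in the TAR (default days 1–28, inclusive), under monthly
accrual — only exposures and events recorded before the accrual boundary
are visible and the TAR is clipped at the boundary.

Conventions chosen where the design was genuinely open: ages are taken at
the index day (anchor visit or vaccination); the unanchored historical
side, which has no per-person index, uses age at the interval start — so a
person can change bands between windows, leaving a small residual after
adjustment (visible only under steep age gradients). The anchored
background TAR is clipped to the observation period but not to the
historical interval; for 12-month configurations an anchor in the last 28
days of the interval can therefore reach a few days past it
(≈ 28/360 of anchors, half of those days on average) — a deliberate
symmetry with the exposed TAR rather than a claim about the original
design.

## Positive controls

For each negative control with at least `min_outcomes = 25` first events
among exposed TARs over the full surveillance period, and each target IRR
`r ∈ {1.5, 2, 4}`, a positive control copies the parent's events and adds,
per vaccinated person, events from a homogeneous process at rate
`(r−1)·λ̂` over the person's TAR, where `λ̂` is the parent's marginal
exposed-TAR first-event rate. This preserves the target *marginal* IRR in
expectation with a constant hazard ratio across days 1–28. The baseline
estimator is the marginal rate, not a per-person fitted hazard — the
evaluation consumes marginal IRRs, and a model-based baseline would add
machinery without changing what is being tested. First-event logic is
applied *after* injection, as an estimator would see real data.

## Estimation

For one (control, design, month) cell with observed count `O`, expected
count `E` and historical event count `n_hist`:

* `IRR = O/E`, `se(log IRR) = sqrt(1/O + 1/n_hist)`, Wald 95% CI on the
  log scale (a normal-theory CI is required downstream by calibration);
* exact one-sided Poisson tail `p = P(X ≥ O)`, `X ~ Poisson(E)`, treating
  `E` as fixed (the standard conditional surveillance construction;
  historical sampling error enters only through the standard error);
* MaxSPRT Poisson `LLR = O ln(O/E) − (O−E)` for `O > E`, else 0.

Cells with `O = 0`, `E ≤ 0`, or no exposed person-time are flagged
non-estimable and carried through — never dropped, never an exception.
Signals are one-sided (`p < 0.05`): the method is an elevated-risk
detector. Sequential critical values for the LLR are out of scope; the LLR
is reported as a statistic.

## Empirical calibration

Each control estimate minus its known true log IRR is a bias observation
`b_i` with sampling error `se_i`. The systematic error model is the
convolution `b_i ~ N(μ, σ² + se_i²)`, fitted by maximum likelihood on
`(μ, log σ)` with bounded quasi-Newton from three starts
(`(0,−2)`, `(0,0)`, `(median b, log MAD)`); `σ` is bounded below at
`e^{−12}` ≈ 0 and convergence is reported, with non-converged models
passing estimates through uncalibrated. The systematic error is assumed
constant in the true effect size, which licenses pooling negatives and
positives after truth subtraction.

Calibrated quantities shift by `μ` and widen by `σ`:
`log IRR_cal = log IRR − μ`, `se_cal = sqrt(se² + σ²)`,
`p_cal = 1 − Φ((log IRR − μ)/se_cal)`. Leave-one-out refits the model
excluding the control being calibrated — and by default its entire parent
family, since positives are built from their parent's events and would
otherwise leak nearly identical information into their own null
distribution (`loo_family = FALSE` restores the literal self-only rule).
The "calibrated LLR" decision is realized as thresholding `p_cal` at α:
the metrics consume decisions, and no calibrated-LLR statistic is defined
in the underlying method.

## Metrics and estimability

Type 1 error = share of estimable negative controls with `p < 0.05`;
type 2 error = share of positives with `p ≥ 0.05` (overall and per IRR);
AUC = Mann–Whitney rank AUC of log IRR scores with ties counting ½;
coverage = share of controls whose true IRR lies in the 95% CI; geometric
mean precision = `exp(mean(ln 1/se²))`; MSE on the log-IRR scale.
Negative controls whose monthly population rate satisfies
`max/min > 1.5` across surveillance months with non-zero rates are
excluded ("rate changing by more than 50% over time", read as the
strictest symmetric ratio rule); zero-exposure and zero-expected cells are
flagged, and every exclusion is logged with its reason. Timeliness reports,
per positive control, the earliest accrual month with a signal; positives
never detected within follow-up are censored at `n_months + 1` when
averaging.

## A structural property worth knowing: first-event depletion

Background rates are first-event rates over a 270–360 day interval while
observed rates are first-event rates over a 28-day TAR. At hazard λ the
first-event rate over a window of length T is `(1 − e^{−λT})/T < λ`, so
the longer historical window depletes more: the O/E ratio of a perfectly
unbiased recurrent-event process is biased upward by roughly `λ·T/2` of
the historical window. At adverse-event-of-special-interest rates
(≤ 0.1/person-year) this is under 2% and invisible; at 0.2/person-year it
already adds ≈ +4% log-bias and measurably inflates type 1 error, and
under steep age gradients it distorts stratified background rates in the
oldest bands. The benchmark's default scenarios therefore use rates in the
AESI range (0.03–0.1/person-year); the effect itself is a real property of
historical-comparator designs with first-event background rates, not an
artifact of this implementation.

## Numerical and tie-break choices

* Accrual months are 30-day blocks; the 365-day historical offset and
  365.25-day year are used for mirroring and person-time respectively.
* Age bands `[0,10), …, [80,90), [90,∞)`, band index capped at 9.
* The anchored design picks its random visit with a seed derived from the
  scenario seed, so repeated analyses of the same tables agree.
* The rapid uptake curve is (0.60, 0.25, rest uniform) over months; the
  slow curve is uniform.
* `p ≥ 0.05` counts as "missed" for type 2 error (ties have probability
  zero in theory and are folded into the miss side).
* The dominating-bound thinning in the outcome generator uses each
  person's maximum age multiplier over their observation span, the
  seasonal maximum `1 + A`, and the secular extreme, so acceptance
  probabilities are exact.

## Known limitations

Monthly accrual approximates calendar months by 30-day blocks; there is no
within-database heterogeneity, no misclassification of injected events
(the method's own stated assumption), no sequential alpha-spending for the
LLR, and the CI/p pair mixes an exact conditional test with a Wald
interval — internally documented, not perfectly mutually consistent, but
the construction calibration needs. All empirical claims in this vignette
are computed by the test suite or the acceptance script; none are imported
from elsewhere.
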