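---
title: "Methods: day-level prescription coverage and program-effect estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-level prescription coverage and program-effect estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxcover)
```

This vignette documents the models, rules and numerical choices behind
`rxcover`, in the spirit of a statistical methods appendix. It states no
empirical result that the package's tests do not themselves compute.

## Estimand and observation structure

The package evaluates a clinic adherence-support program from routinely
collected pharmacy data. The outcome is **prescription coverage**: a
patient-day is covered when the patient's valid prescriptions, if filled
and taken as prescribed, supply the full regimen on that day. Coverage
is a ceiling on pill-taking adherence — the clinic knows what was
prescribed, not what was swallowed — but it is computable from records
every clinic keeps, and lapses in it flag treatment interruptions.

Every day a patient is observed contributes one row, so patients are
weighted by observation time. Observation runs from the earlier of (a)
the day after the patient's first recorded prescription ends and (b) the
day of the second recorded prescription — whichever establishes that
care has begun — bounded below by the observation-period start
(2013-07-01 by default), and ends at the earlier of transfer-out and the
end of pharmacy data (2014-06-26). Patients whose window is empty have
no observable person-time and are excluded, tallied under
`no_observation_time`.

The exposure contrast is **intention to treat**: `Exposed` patients had
a phone number captured into the program database before the observation
period (and were therefore sent messages), `Unexposed` patients had a
chart with no number, `Unknown` patients had no reviewable chart.
Opt-out and delivery failure are deliberately ignored; they are
post-assignment events, and conditioning on them would break the
assignment-based contrast. The program-effect parameter is the
group-by-period interaction: the change in coverage odds from the
pre-program period (the roughly two months before launch) to the
during-program period in the exposed group, relative to the same change
in the unexposed group. A difference-in-differences structure absorbs
both stable group differences and secular period trends.

## The coverage engine

Coverage is computed by simulating a scalar balance of remaining
coverage days across a patient's deduplicated prescription history,
which may begin before the observation window (history informs the
balance at window start):

* A prescription of $d$ days issued on day $t$ covers $[t, t+d-1]$; all
  intervals are closed and counted inclusively.
* At each issue, the balance remaining from the previous prescription is
  credited **only if the agent set is unchanged**, and capped at the
  carryover limit (30 days by default, a clinic policy): with 15 days
  remaining, a new 30-day same-regimen prescription yields 45 days of
  coverage; with 45 days remaining it yields 60, the cap binding. A
  regimen change forfeits the carryover entirely. The cap is applied to
  the carried-over remainder before the new duration is added; the
  policy's worked example (15 + 30 = 45) is consistent with this reading
  and does not distinguish it from capping after addition, which would
  differ only for prescriptions shorter than the shortfall.
* The balance decays one day per calendar day, between issues as well as
  during gaps; a day is covered while the balance is positive.
* Agent sets are compared as unordered, case-insensitive sets of drug
  codes. The fixed-dose-combination flag is packaging metadata and never
  enters set equality.

Two boundary conventions are fixed once: the program launch day itself
is labeled `during_program` (the pre-program period is
`[obs_start, program_start - 1]`, 70 days at the defaults), and ages are
fractional years at the start of data availability.

**Duplicates.** Pharmacy systems sometimes re-record the remaining
balance of a six-month prescription (e.g., a 3-month record entered 3
months in). The rule is formalized as *interval containment with an
identical agent set*: a record is dropped when an earlier kept record
with the same agents wholly contains its coverage interval. Containment
is the conservative formalization — a later record that extends past the
earlier one's end adds real information and is kept.

**A caveat on monotonicity.** Adding a prescription does not always
weakly increase coverage: with more than the cap remaining, a new
same-regimen prescription caps the remainder, and a *different*-regimen
prescription resets it, either of which can uncover later days. This is
a direct consequence of the cap/forfeit policy, not an implementation
artifact; the engine's tests therefore assert monotonicity only where it
holds (days before the added prescription's issue) and verify the full
semantics against an independent day-by-day inventory oracle on 1,000
random histories.

## Cohort construction

Inclusion criteria are applied in a fixed order — under adult age (18
years at the data-availability start); no prescription issued during the
observation period; enrollment after the observation period began; phone
number captured only after the observation period began; no observable
person-time — and each excluded patient is counted once, under the first
matching reason. The order matters only for the tally (a patient failing
two criteria must be counted somewhere); the included set is identical
under any order. The tally's conservation (included = screened − sum of
exclusions) is enforced by its constructor.

Missing non-prescription covariates (age, gender) are replaced by the
cohort mean of available values — for a 0/1-encoded covariate the mean
is fractional — and an indicator flags members with any substituted
value. Mean substitution preserves each covariate's mean and is the
pragmatic choice when missingness is sparse (the generator's default is
2% per field); the indicator lets the model absorb any residual
difference. Multiple imputation is out of scope.

Descriptive comparisons follow the conventions of baseline tables in
clinical cohort studies: continuous variables summarized as median (IQR)
but compared by one-way ANOVA, categorical variables as n (%) compared
by chi-squared, with both an all-groups and an Exposed-vs-Unexposed
column (the latter using the two-group versions of the same tests). The
proportion of patients above 95% coverage, pre versus during program, is
compared by an exact binomial McNemar test on discordant pairs among
members observed in both periods.

## The mixed-effects model

With reference levels `group = Unexposed` and `period = pre_program`,
the model

$$\operatorname{logit} P(\text{covered}_{it} = 1) = \beta_0 +
\gamma_p \cdot \text{during}_t + \gamma_E \cdot E_i + \gamma_U \cdot U_i
+ \delta_E \, E_i\,\text{during}_t + \delta_U \, U_i\,\text{during}_t +
\mathbf{x}_{it}'\boldsymbol\beta + u_i, \qquad u_i \sim N(0, \sigma_u^2)$$

makes every reported contrast a single coefficient: $e^{\gamma_E}$ and
$e^{\gamma_U}$ are pre-program (baseline-adherence) group contrasts,
$e^{\delta_E}$ and $e^{\delta_U}$ the program effects. Candidate
covariates $\mathbf{x}_{it}$ — age, gender, prior ART duration and
active prescription length in 30-day units (both time-varying, the
latter carried forward from the most recently issued prescription,
including across uncovered gaps, since covariate values on uncovered
days are otherwise undefined), regimen line, fixed-dose combination, and
the missingness indicator — are pruned by stepwise backward elimination:
repeatedly drop the single candidate with the largest Wald p-value above
0.25, refit, stop when all candidates are at or below the threshold. The
a priori terms (group, period, interaction) are never candidates. Wald
standard errors, 95% intervals and p-values are used throughout,
including in elimination.

Numerical choices:

* Fitting is delegated to `lme4::glmer` (bobyqa optimizer).
  Patient-days with identical covariate values are collapsed to binomial
  counts first — an exact likelihood identity that reduces a
  model-faithful simulation from $10^5$ rows to two rows per patient.
* `backward_eliminate()` and `run_analysis()` default to `nAGQ = 0`
  (fixed effects profiled inside the penalized least-squares step).
  With hundreds of days per patient the difference from the Laplace fit
  (`nAGQ = 1`) is negligible — the test suite includes a degenerate-limit
  check — while full-cohort daily datasets fit in seconds rather than
  minutes. `fit_coverage_model()` itself defaults to `nAGQ = 1`, which
  is what the recovery studies use.
* Covariates without variation in a subset are dropped as inestimable;
  a constant outcome or a single represented group is an explicit error;
  optimizer convergence messages are carried on the result object and
  printed, never swallowed.
* Days per year is 365.25.

**Absolute translation.** For an observed average coverage $p$ and
program-effect odds ratio $R$, the hypothetical no-exposure coverage is
$p' = (p/(1-p)/R) / (1 + p/(1-p)/R)$ and the absolute effect is
$(p - p')\times 365.25$ days per year. The translation is exact odds
arithmetic: zero at $R = 1$, strictly increasing in $R$, and invertible.
At $p = 0.941$ and $R = 1.23$ it gives 4.60 days per year (4.7 when
computed from unrounded model estimates rather than these rounded
inputs).

## The synthetic clinic generator

No patient-level data are distributed with the package; the generator
provides cohorts with the statistical structure the analysis assumes.
Defaults emulate a rural South African government ART clinic of the
program era: 2,255-patient scale (default runs use 300), exposure mix
78.5 / 14.0 / 7.5%, 70% female, age log-normal matched to median 37.7
(IQR 32.4–43.9), prescription lengths mixed over 1/2/3/6 months
dominated by 6-month scripts (59%), 94.6% first-line, fixed-dose
combinations rare initially (1.6%) with a during-program rollout ramp,
3.4% transfer-out, and duplicate re-recording of half the 6-month
prescriptions. Every generated table passes the package's strict
validation, and per-patient substreams derived from the seed make output
deterministic with patient-wise independence (adding a patient never
perturbs the others).

**Behavioral mode** simulates the refill process: at each prescription's
scheduled end the next issue is on time with probability
$\operatorname{logit}^{-1}(\alpha + u_i + \eta \cdot \text{Exposed}_i
\cdot \text{during}_t)$ ($u_i$ a refill-level patient intercept with SD
`sigma_u`), delayed by a geometric gap (mean 12 days) otherwise, and
sometimes early (25%, mean 7 days), which exercises the carryover cap.
The effect $\eta$ cannot be set analytically — inverting daily-coverage
odds into refill-gap distributions is intractable — so it is
**calibrated** by bisection (`calibrate_gap_effect()`): simulate a large
clinic, push it through the full pipeline, fit the unadjusted
group-by-period model, and move $\eta$ until the realized interaction
odds ratio matches `true_effect_or` within 2%. The shipped default
(`gap_effect = 0.5625`) was frozen from one such run at the default
settings with 6,000 calibration patients (realized OR 1.26 against the
1.25 target; the covariate-adjusted estimate at the same scale was
1.245).

**Model-faithful mode** draws patient-day outcomes directly from the
mixed logistic data-generating equation, bypassing prescriptions. It
exists because behavioral data cannot support exact recovery tests: in a
refill process, uncovered days arrive in runs, so the daily model is
*serially misspecified* for them — the estimated random-intercept SD on
the daily scale is several times the refill-level `sigma_u`, Wald
standard errors understate replicate-to-replicate spread, and
single-cohort interaction estimates scatter widely around the calibrated
target (the suite checks one cohort-scale behavioral replicate against a
band reflecting that spread, and the calibrated target itself at the
calibration scale). The same caveat applies to real pharmacy data and is
a known cost of the patient-day design; the published analyses it
follows accept it for the temporal resolution it buys. In
model-faithful mode the model is exactly true, so the package's
operating characteristics are testable at nominal levels: across 100
replicates at the defaults (300 patients, effect OR 1.25, σᵤ = 0.8), the
95% interval for the interaction OR must cover the truth with empirical
coverage in [0.90, 0.99], null replicates must center on 1, and with
σᵤ = 0 the mixed fit must agree with ordinary logistic regression.

What the generator does **not** emulate: drug stock-outs, seasonal
attendance patterns, dependence between prescription length and
underlying adherence (independence is assumed), within-prescription
pickup dynamics (six-month prescriptions dispensed as two pickups are
represented by the prescription record, which is what defines coverage),
and any behavioral response to opt-out or delivery failure (inert under
intention to treat). Passing tests on synthetic data therefore validate
the *machinery* — rules, estimator, translation — not the substantive
findings of any particular clinic.

## Problem sizes and determinism

The test suite runs the oracle equivalence on 1,000 random histories,
parameter recovery on 100 model-faithful replicates of 300 patients,
pipeline smoke and determinism runs at 60 patients, and one
2,000-patient behavioral replicate; these sizes were chosen so the whole
suite completes in minutes on a laptop while keeping Monte Carlo error
well inside the asserted bands. All analytic output is deterministic
given inputs, configuration and seed; `run_pipeline()` writes a manifest
(input digests, stage timings, counts, convergence flags) with every
run, and identical inputs reproduce identical report bytes.

## Known limitations

* Coverage is an upper bound on adherence; the model cannot distinguish
  non-pickup from non-ingestion.
* The serial-correlation misspecification above means σᵤ estimated from
  daily data should not be interpreted as pure patient heterogeneity.
* Backward elimination's selection noise is inherited from the design it
  reimplements; eliminated-covariate reports should be read as model
  housekeeping, not evidence of no effect.
* The exclusion-order convention affects only the tally attribution,
  and the recent-initiator boundary (730.5 days, inclusive) is a
  convention; neither affects membership of the full cohort.
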