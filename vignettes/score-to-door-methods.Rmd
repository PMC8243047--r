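---
title: "Methods: quantifying Score-to-Door time and its association with outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Score-to-Door time and its association with outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(scoretodoor)
```

## The question

Most unplanned critical-care admissions from hospital wards are preceded by a
measurable trajectory of physiological deterioration. Rapid response systems
are built on the premise that shortening the interval between the onset of
that deterioration and definitive critical care improves outcome, yet most of
the supporting literature starts the clock at the *decision to admit* or at
emergency-department arrival — well after deterioration began. The
"Score to Door" (STD) time starts it instead at the first National Early
Warning Score (NEWS) high trigger, and this package operationalises the whole
analysis: scoring, cohort derivation, exposure computation, and the
regression models that adjust the exposure–outcome association for sickness
severity, comorbidity, frailty and logistic factors.

## NEWS scoring

NEWS aggregates six physiological parameters — respiratory rate, oxygen
saturation, systolic blood pressure, heart rate, level of consciousness and
temperature — each banded into ordinal component scores 0–3, plus a weighting
of 2 when the patient receives supplemental oxygen. The total ranges 0–20.
The package ships two charts as declarative YAML band tables:
`news2_scale1` (the 2017 revision, SpO~2~ Scale 1; the default) and
`news_2012` (the original chart). Their numeric bands coincide; the revision
changed the consciousness ladder (adding new-onset confusion, which scores 3
like any other non-alert state) and introduced an SpO~2~ scale for
hypercapnic respiratory failure that is deliberately *not* implemented here —
the cohort definition below depends only on the thresholds 7 and 5, which
both charts share. Which chart a site actually ran during a multi-year study
window is often unknowable, so the version is a configuration flag rather
than a hard-coded assumption.

Two numerical conventions matter:

* bands are half-open intervals $[lo, hi)$ which, with integer vital signs
  and one-decimal temperatures, reproduce the inclusive printed charts
  exactly (e.g. the `[38.1, 39.1)` band is the chart's "38.1–39.0 °C");
* out-of-range values (an SpO~2~ of 110%) are **rejected, not clamped**.
  Clamping would silently convert a transcription error into a plausible
  vital sign and corrupt cohort derivation downstream.

`validate_band_table()` enforces the structural invariants (contiguous
partition, components in 0–3) so user-supplied charts fail loudly at load.

```{r}
bands <- news_bands()
max_attainable_score(bands)
score_observation(list(respiratory_rate = 22, spo2 = 93, on_oxygen = FALSE,
                       systolic_bp = 105, heart_rate = 95,
                       consciousness = "alert", temperature = 38.5))
```

## Cohort derivation

The analysis population is unplanned adult critical-care admissions from a
level-1 ward with *new and sustained* physiological derangement:

1. **Pathway** — the event immediately preceding the critical-care episode
   must be a ward stay: admissions direct from the emergency department, or
   with an intervening operating-theatre visit, are excluded.
2. **Sustained trigger** — the earliest observation scoring ≥ 7 such that no
   later observation before admission scores < 5. "Did not decrease below 5"
   is read literally: a score of exactly 5 is tolerated. A single qualifying
   observation satisfies the condition vacuously.
3. **Exposure cap** — Score-to-Door time of at most 168 h (7 days),
   inclusive.
4. **Complete case** — all analysis covariates and outcomes present.
   Patients failing only this step are retained, flagged, for the
   imputation sensitivity analysis.

Each patient is counted once in the exclusion ledger, at the first failing
step, so the ledger always sums to the number screened. The trigger search
starts at hospital admission (the descriptive "time from hospital admission
to first high score" is defined from the same origin), observations
timestamped exactly at the critical-care door are outside the pre-admission
interval (half-open again), and the admission itself is timed by the *first
recorded heart rate* in critical care — an observation-based surrogate that
avoids administrative timestamp error. Only the first qualifying
critical-care admission per hospital stay defines the index episode. The
exposure is

$$\mathrm{STD} = t_{\text{first heart rate in critical care}} -
  t_{\text{trigger}} \quad \text{(decimal hours, } > 0 \text{)}.$$

Out-of-hours is the whole weekend
$[\text{Sat } 00{:}00, \text{Mon } 00{:}00)$ plus weekday nights
$[20{:}00, 24{:}00) \cup [00{:}00, 08{:}00)$; the half-open windows
integrate to exactly $48 + 5 \times 12 = 108$ hours per week, which the test
suite checks on a minute grid.

The trigger detector runs in $O(n)$ using a suffix minimum (an observation
qualifies iff its score ≥ 7 and the minimum over all later pre-admission
scores is ≥ 5) and is tested for exact agreement with an $O(n^2)$
brute-force scan on thousands of random score sequences.

## Statistical models

The modelling follows a conventional two-stage build per mortality outcome
(critical-care death during the index episode; hospital death):

* **Descriptives** — median [IQR] with Mann–Whitney U for continuous
  variables; count (%) with two-sided Fisher's exact for binary ones. The
  Mann–Whitney p-value is computed by exact enumeration over all group
  assignments (mid-ranks for ties) when both groups have ≤ 8 observations,
  and by the tie-corrected normal approximation otherwise. Fisher's exact
  uses the point-probability two-sided rule of `stats::fisher.test`.
* **Univariable screen** at $p < 0.2$, same family as the final model.
  Candidates showing separation or non-convergence are dropped with a
  warning rather than aborting the run.
* **Multivariable model** containing the screened-in variables *plus the
  Score-to-Door exposure, forced* regardless of its screen p-value, since
  the exposure is the question, not a nuisance. The intercept is always
  fitted and reported.
* **Log-linear models** for critical-care length of stay (natural-log
  transformed, fitted on critical-care survivors only — length of stay for
  decedents measures time to death, a different quantity) and for the
  determinants of the exposure itself. Predictors here are chosen for
  plausibility, not screened.
* Final significance at $p < 0.05$, two-sided throughout.

A logistic coefficient $\beta$ is reported as the odds ratio $e^\beta$ per
unit (per hour of exposure, per year of age, ...). A log-linear coefficient
is reported as the percent change $100(e^\beta - 1)$ per unit. The
small-coefficient shorthand $100\beta$ is also exposed
(`percent_effect(beta, method = "abs")`) because published reports sometimes
quote $|\beta| \times 100$ — e.g. a coefficient of $-0.079$ is $-7.6\%$
under the exact transform but is often verbalised as "7.9%". The exact
transform is the default and the two agree to first order.

### Bootstrap confidence intervals

Confidence intervals for the multivariable models use the bias-corrected
accelerated (BCa) bootstrap over case resamples of patient rows (one row per
patient by construction), default $B = 2000$ with a mandatory seed, so every
run is bit-reproducible. The implementation computes the bias-correction
constant $z_0$ from the share of replicates below the full-sample estimate
and the acceleration $a$ from the skewness of the case-deletion influence
values (`stats::dfbeta`), the standard jackknife approximation; adjusted
percentiles are interpolated on the normal-quantile scale. Resampled refits
use the precomputed design matrix (`glm.fit`/`lm.fit`), which is the same
estimator as the formula interface at a fraction of the cost. With $B = 0$
the model reports analytic Wald intervals and labels them as such — a
documented fallback, never a silent substitution. Against the `boot` package
on identical replicates of a sample mean, the intervals agree to well within
Monte-Carlo resolution.

### Sensitivity analysis

The complete-case decision is probed by re-fitting every final model on a
version of the cohort in which each missing covariate cell is replaced by
the median of the observed values of its variable, and comparing the
significance flag of every term between the two fits.

## The synthetic ward-EHR generator

No patient-level data can ship with the package, so the generator is a
first-class, tested module that emulates the study conditions end to end:

* a configurable number of screened critical-care admissions, partitioned
  into pathway categories with default fractions matching the published
  inclusion flow (≈ 50% direct from the ED, ≈ 39% never sustaining a high
  score, ≈ 1.3% with a missing covariate, 0.5% beyond the 7-day cap);
* trigger-to-door latency drawn lognormal(meanlog 1.8406, sdlog 0.7320) —
  median 6.3 h, IQR ≈ 3.8–10.3 h, the published exposure distribution; a
  gamma alternative is selectable;
* onset of deterioration lognormal in days from admission (median 3.3 d,
  IQR ≈ 1.1–10.3 d); triggering NEWS values drawn from a distribution with
  median 8, IQR 7–9;
* covariate marginals (age, Charlson–Deyo, frailty, day-1 SOFA, ventilation,
  sepsis, admission type) matched to the published descriptive table;
* outcomes generated from explicit regression models: critical-care death
  from a logistic model with a per-hour odds ratio of 1.02 on the exposure
  (intercept −4.415, solved once so the marginal mortality is the published
  16.3%), hospital death adding an independent post-critical-care hazard,
  and length of stay from a log-linear model (0.012 per hour) with Gaussian
  log-scale noise.

Trajectories are constructed in **score space**: each observation slot gets
a target total (baseline 0–4 on the ward, a short 5–6 ramp, the trigger
value, then a sustained ≥ 5 plateau — or, for the "not sustained" category,
either a 5–6 plateau that never reaches 7 or a reached trigger deliberately
disqualified by a later sub-floor reading). The total is then decomposed
into feasible component scores and each vital sign is sampled uniformly
inside a band realising its component. This guarantees the
construction-versus-detection round trip — every generated "included"
patient is detected with exactly the intended trigger time and score, every
violator is excluded at exactly the intended ledger step — which the test
suite asserts patient by patient. The price is realism: vitals jump within
bands rather than drifting smoothly, there are no circadian rhythms,
interventions or treatment responses, observation timing is protocolised
(≈ 6-hourly at low scores, hourly when high), and missingness is strictly
completely-at-random in four covariates. Passing tests therefore demonstrate
that the *pipeline* is correct under known generating conditions — not that
real EHR extracts are this clean.

## Calibration checks and problem sizes

The package's own calibration suite (run by the tests) uses problem sizes
chosen to balance Monte-Carlo resolution against a desktop-scale run:

* scorer equivalence against an independently written reference-chart
  linear search on 10,000 random observations, and trigger-detector
  equivalence against the quadratic brute force on 1,000 random sequences;
* screen behaviour under the null: a candidate generated independently of
  the outcome is retained in ≈ 20% of 2,000 replicates (the screening
  alpha), and the forced exposure's final-model p-value falls below 0.05 in
  ≈ 5% of null replicates;
* parameter recovery: 20 replicates of the full pipeline
  (simulate → score → derive → fit, n = 5,000 patients each, $B = 600$)
  recover the generating per-hour log-odds ln(1.02) and log-LOS coefficient
  0.012. Bias is assessed with a two-sided test at the 1% level against the
  Monte-Carlo standard error (a literal "bias smaller than one SE" bound
  would fail by chance about a third of the time for an unbiased
  estimator), and BCa coverage of the generating value is required in at
  least 16 of 20 replicates (nominal 95%, binomial floor at the 0.3% level).

## Known limitations

* The cohort definition is deliberately strict; nothing here generalises to
  patients with lower NEWS triggers, and the package makes no causal claims
  — it reproduces an observational adjustment.
* SOFA, Charlson–Deyo and frailty scores are consumed as supplied
  covariates; computing them from raw sources is out of scope, as are
  ICD-10 grouping and sepsis coding.
* The NEWS2 SpO~2~ Scale 2 (hypercapnic targets) is not implemented.
* Single hospital stay per patient: readmission chains beyond the index
  critical-care episode are not modelled.
* The generator's violation categories are mutually exclusive by
  construction; real patients can fail several criteria at once (the ledger
  would still count them once, at the first failing step).
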