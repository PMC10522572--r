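---
title: "Methods: nested case-control analysis of cumulative drug exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested case-control analysis of cumulative drug exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design

`nestcc` implements a nested case-control analysis of cumulative drug
exposure and cancer risk, in the setting of antipsychotic users and incident
lung cancer. The study base is a cohort of antipsychotic initiators drawn
from longitudinal dispensing and diagnosis records. Cases are cohort members
with a first lung-cancer diagnosis (ICD-9 162.x) inside the outcome window;
each case's diagnosis date becomes the *index date* for itself and for up to
ten controls sampled from the risk set at that date — cohort members of the
same sex and the same completed age in years who are alive, cancer-free, and
already exposed to antipsychotics at that date (incidence-density sampling).
Under this sampling scheme the conditional-logistic odds ratio estimates the
rate ratio of the underlying hazard, and a patient may serve as a control
before later becoming a case.

## The model

With one case and $m_s$ controls in set $s$, covariate rows $x_{sj}$ and the
case in position $j = 0$, the conditional likelihood is

$$
L(\beta) \;=\; \prod_s
  \frac{\exp(x_{s0}^\top \beta)}{\sum_{j=0}^{m_s} \exp(x_{sj}^\top \beta)} .
$$

Because every set has exactly one case, no ties arise and this is also the
exact (and the Breslow) partial likelihood. `cclogit()` maximizes it by
Newton–Raphson from $\beta = 0$ with step-halving (at most 10 halvings per
iteration), stopping when the gradient max-norm falls below $10^{-8}$ or
after 50 iterations. The gradient and Hessian are analytic,

$$
\nabla \ell = \sum_s \left( x_{s0} - \mathbb{E}_\beta[x \mid s] \right),
\qquad
\nabla^2 \ell = -\sum_s \mathrm{Cov}_\beta[x \mid s],
$$

with softmax weights computed after subtracting the within-set maximum of
the linear predictor, so the exponentials cannot overflow. Standard errors
come from the inverse observed information at the optimum; odds ratios and
95% confidence intervals use the fixed normal quantile 1.959964 so that
confidence limits are bit-stable across platforms. Any coefficient with
$|\hat\beta| > 15$ at termination flags the fit `"suspect_separation"`
rather than being penalized. Sets whose members all share identical rows are
non-informative (they contribute a constant); a design with no informative
set is an error, and aliased columns are detected on the *set-centered*
design matrix (only within-set contrasts identify the likelihood) and
dropped before fitting.

Two regression designs are built by `build_design()`:

* **analysis one** — two indicators for cumulative flupentixol exposure
  (366–1825 and 1826+ days; reference 0–365), two indicators for cumulative
  exposure to antipsychotics other than flupentixol (same cuts, reference
  0–365), and the 21 confounder flags: 25 columns;
* **analysis two** — two indicators for cumulative any-antipsychotic
  exposure (reference 1–365 days) and the 21 confounders: 23 columns.

## Cumulative exposure

Exposure is counted in *distinct calendar days covered by at least one
prescription interval* before the index date. Conventions:

* closed-interval day counting: a prescription from $s$ to $e$ covers
  $e - s + 1$ days, so a same-day script is one day of exposure (the design
  requires at least one day of exposure of every member);
* truncation at index date $-$ 1: exposure on or after the diagnosis day
  never counts;
* overlapping prescriptions contribute each day once (`union_days()`, a
  sort-and-sweep over interval endpoints). Within a single drug group the
  same union rule is applied by default; because summing raw durations of
  overlapping same-drug scripts can exceed calendar time, we treat the union
  as the scientifically meaningful quantity, but
  `study_config(within_drug_union = FALSE)` restores the raw-sum reading.

Records with incomplete dates go through a three-level hierarchy
(`resolve_durations()`): (1) both dates present — use as recorded; (2) one
date missing but dosage, frequency and quantity present — duration is
$\lceil \text{quantity} / (\text{dosage} \times \text{frequency}) \rceil$
days anchored at the known date (dosage = units per administration,
frequency = administrations per day, quantity = total units, which is what
makes the formula well-defined); (3) otherwise the per-drug median duration
of complete records, with a global-median fallback. A record with neither
date has no anchor and is dropped with a warning rather than being imputed
to an arbitrary position. Cumulative exposure is categorized at the
cut-points 365 and 1825 days, following treatment-duration guidelines of
one to five years.

## Screening and matching

`screen_cohort()` applies four exclusions in a fixed order, each patient
counted once at the first rule that removes them: (1) structurally invalid
demographics — an *empty* death date means alive at database end and is not
an exclusion; (2) death before the first antipsychotic prescription;
(3) lung cancer *on or before* the first antipsychotic prescription;
(4) lung cancer before the outcome window (the first two study years act as
a screening period against prevalent cancer). Membership of the final set is
order-invariant; the order only attributes counts in the attrition log.

`match_controls()` processes cases in ascending index date (ties by patient
id) and samples `min(ratio, available)` controls uniformly without
replacement from the eligible candidates whose use count is below the reuse
cap (default 4; `Inf` reproduces the unlimited-reuse sensitivity analysis).
Sampling draws from the lexicographically sorted candidate list under a
seeded generator, so a run is a deterministic function of the inputs and the
seed. Controls must be alive at the index date: risk-set membership requires
being at risk at that date, which is the design choice we adopt where the
convention is sometimes left unstated. Cases
with no eligible candidate are dropped and logged — a singleton set has an
undefined conditional likelihood. Age matching is exact in completed years,
the strictest reading of matching "by age in years".

## Confounders

Twenty-one binary flags (4 co-medication classes, 17 diagnoses) are
ascertained over `[2001-01-01, index_date]`, upper bound inclusive — the
plainest reading of ascertainment "between 2001 and the index date" — with
`covariate_window_inclusive = FALSE` available for the strict alternative.
The shipped codelists are synthetic placeholders aligned with the codes the
generator emits; they are configuration, not clinical authority, and
real-data users must supply their own.

## The synthetic generator

`sim_ehr()` emulates the statistical structure the analysis assumes, not any
real database: per-patient dispensing episodes (negative-binomial count,
lognormal lengths, exponential gaps, a configurable fraction starting before
the previous episode ends, which is what makes union counting testable),
about 2% of episodes missing the end date completely at random (half of
those keeping dispensing fields so arithmetic imputation is exercised, half
keeping only the drug code), binary comorbidity/co-medication indicators,
and a lung-cancer outcome simulated on a 30-day discrete-time grid from the
first prescription: at each step the *current* cumulative any-antipsychotic
exposure category is computed and cancer occurs with probability
$\mathrm{logit}^{-1}(\alpha + \beta_2 I[\text{366–1825}] +
\beta_3 I[\text{1826+}] + \gamma^\top z)$, with death as a competing event
on the same grid (cancer checked first within a step). Uniform draws are
laid out independently of the effect parameters, so runs with the same seed
share their randomness (common random numbers): raising an effect can only
add or advance events, a property the tests assert directly.

Default parameters are the package's one-time choice of a realistic chronic
antipsychotic cohort, with the episode process set so that the control
exposure-category mix approximates the published prevalences
(roughly half of controls under one year of cumulative exposure and a fifth
above five years): 35 expected episodes of median length 75 days with heavy
between-patient dispersion, 25-day mean gaps, 20% overlap probability, 10%
flupentixol users, baseline hazard logit −8.3 per 30-day step (about 2%
cumulative incidence), true odds ratios 0.5 (366–1825 days) and 0.6 (1826+
days), and per-step death probability 0.003. The generator does **not**
emulate smoking behaviour (absent from the source records too), dosing
pharmacology, indication bias, or private-sector care fragmentation — so
passing recovery tests show the *estimator* is correct under the stated
sampling model, not that real-data estimates are unconfounded.

## Validation problem sizes

The package validates itself at sizes chosen to balance statistical
resolution against a single-CPU run: exact day-set enumeration against the
sweep union on 1,000 random interval sets; grid-search and 1:1
difference-logistic oracles for the likelihood; one full-pipeline run at
50,000 patients for the point-estimate check (true OR 0.5 recovered within
[0.40, 0.625]); 100 seeded replicates at 8,000 patients for 95% CI coverage
(at least 90 of 100 must cover both true ORs); and 200 null-effect Wald
tests (100 replicates, two exposure terms) at 4,000 patients for size
calibration (accepted rejection rate 2–10%). Coverage and size of a
correctly specified conditional likelihood do not depend on the cohort size,
only the width of the intervals does.

## Known limitations

* The conditional likelihood here assumes exactly one case per set; it does
  not implement tie corrections or exact conditional inference for other
  designs.
* Exposure is duration-based only; dose-standardized exposure (e.g. DDDs)
  is out of scope.
* The attrition of patients whose candidate pool is exhausted by the reuse
  cap makes matching order-sensitive; the fixed processing order makes this
  reproducible rather than removing it.
* Placeholder codelists mean absolute covariate prevalences in synthetic
  runs are illustrative, not clinically calibrated.
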