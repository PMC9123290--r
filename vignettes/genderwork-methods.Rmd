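---
title: "Methods: modelling sex and gender inequalities in depressive symptoms among older workers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling sex and gender inequalities in depressive symptoms among older workers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genderwork)
```

## The scientific problem

Older women leave the labour force earlier than men, and depressive symptoms
— more common in women — are a known risk factor for early work exit. Two
mechanisms could link working conditions to this inequality:

* **differential vulnerability** — men and women (or masculine- and
  feminine-role workers) react differently to the *same* conditions; in a
  regression this is an interaction between the group and the condition;
* **differential exposure** — the groups are exposed to *different*
  conditions, which in turn affect mental health; this is mediation, a
  product of an exposure→mediator path ("a") and a mediator→outcome
  path ("b").

The package separates **biological sex** from **gender**, operationalized as
a composite of six labour-market/household role items. Depressive symptoms
are a CES-D total (0–60) whose floor at zero motivates a left-censored
(tobit) outcome model.

## The gender-role index

Six items, each coded so that a higher value is the more feminine role
profile:

| item | coding | range |
|---|---|---|
| working hours/week | sample quartiles, reversed | 0–3 |
| equivalized household income | sample quartiles, reversed | 0–3 |
| % female workers in sector | fixed bands ≤25 / 26–50 / 51–75 / ≥76 | 0–3 |
| education (ISCED-based) | high 0, intermediate 1, low 2 | 0–2 |
| informal caregiving | none 0, <8 h/wk 1, ≥8 h/wk 2 | 0–2 |
| household chores (min/day) | sample quartiles | 0–3 |

Income is first divided between household members: multiplied by 0.7
(≈ 1/√2) when a partner shares the household, making one- and two-person
households comparable. Quartiles are computed *after* equivalization (the
natural reading of the construction order; both orders are supported).

These literal codings give a total of 0–16. Published descriptions of
closely related indices state a 0–22 range without documenting the extra
codes; since the per-item codings above are the only verifiable
specification, the package implements them literally and leaves the code
tables overridable, rather than guessing at an undocumented variant.

Numerical choices, made once and documented here because no convention is
universal:

* quantiles are linear-interpolation (type-7) — R's default and the most
  widely reproduced definition;
* quartile bands are half-open `[q_k, q_{k+1})` with the top band closed;
* the masculine/feminine split is at the within-sample median of totals by
  default, with ties going to masculine (total > cutoff ⇒ feminine); the
  fixed cutoff 7 (masculine 0–7) is available for replication;
* the same `score > median ⇒ high` tie rule dichotomizes the six
  working-condition sum scores.

## Tobit regression

The outcome model is a latent-normal regression censored below at zero:
`y* = Xβ + ε`, `ε ~ N(0, σ²)`, `y = max(0, y*)`. The log-likelihood sums
normal log-densities over uncensored rows and `log Φ(−x'β/σ)` over rows at
the floor. Estimation choices:

* parameterization in `(β, log σ)`, removing the positivity boundary;
* start from OLS on the uncensored subset with the residual SD as `σ₀`;
* BFGS with the analytic gradient, then Newton polishing (finite-difference
  Hessian of the analytic gradient) until the gradient ∞-norm is below
  1e-6, with at most 200 BFGS + 50 Newton steps — failures produce
  a `converged = FALSE` fit and a warning, never a silent acceptance;
* standard errors from the inverse observed information; the SE of `σ`
  follows from that of `log σ` by the delta method;
* CES-D is treated as continuous despite being integer-valued, and age is
  centered at the sample mean (this affects only the intercept).

The test suite cross-checks coefficients, scale and standard errors against
an independent left-censored Gaussian fit (`survival::survreg`) to ~1e-6,
and verifies near-nominal (92–98%) Wald coverage over repeated simulation.

## Moderation and mediation

**Moderation** (differential vulnerability): tobit of CES-D on the
dichotomized condition, the group, their product and age, with
male/masculine and low exposure as reference groups; the Wald z on the
product term is the test. The twelve condition × group tests are reported
unadjusted — matching standard presentation — and the report log flags the
multiplicity.

**Mediation** (differential exposure): per condition and exposure,

* a path: logistic `mediator ~ exposure + age`;
* b, c′ paths: tobit `cesd ~ mediator + exposure + age`;
* c path: tobit `cesd ~ exposure + age`;
* indirect effect (ACME): `β_M · mean_i[p̂_i(M=1|T=1) − p̂_i(M=1|T=0)]`,
  each person keeping their own age.

The default ACME is on the **latent** (linear-predictor) scale, where the
product form is exact and mediator recoding provably leaves the ACME
unchanged; the observed-outcome ("expected") scale, which pushes the same
contrast through the censored-normal mean `Φ(z)x'β + σφ(z)`, is available
as an option and is attenuated toward zero by the censoring. Confidence
intervals for the ACME are percentile intervals over seeded nonparametric
resamples of persons (500 by default, matching common practice); BCa
refinements are deliberately out of scope. Resamples in which any path
model fails are dropped and counted; more than 10% failures aborts.
Because `c` comes from a separately fitted model, `c ≈ c′ + ACME` holds
only up to sampling error; the suite bounds the gap by twice the total
effect's standard error at n = 5,000.

## Multiple imputation

Missingness is handled by chained equations with predictive mean matching
for *every* variable type (k = 5 donors, 10 cycles): each incomplete column
is regressed on all other analysis variables and missing cells receive an
observed donor value, so integer scores stay integers and categorical
levels stay legal. PMM-for-everything is a deliberate simplification —
robust, type-safe, and appropriate when the original imputation models are
undocumented. Estimates are pooled by Rubin's rules
(`T = W + (1 + 1/m)B`, Barnard–Rubin-style df). For mediation under MI the
package bootstraps *within* each completed dataset and pools the ACME with
the bootstrap variance as the within-imputation variance — a documented
approximation, since no standard prescription exists for combining the two
resampling layers.

## The synthetic cohort generator

Real data of this kind are typically available only on request, so the
package ships a generator whose defaults emulate the study conditions: 313
persons, 43.5% female, age ~ N(58.9, 2.4²), sex-specific category
frequencies for the six gender items, gender-group-specific prevalence of
"high" working conditions, and CES-D produced as
`round(clip(max(0, Xβ + ε), 0, 60))` with σ = 5.6. Raw item values are
drawn by sampling a category from the sex-specific table and then a uniform
value inside that category's band, so the quartile-coding path is exercised
for real. Default outcome coefficients place the effect on feminine gender
(+1.85 latent points) with working-condition effects of −0.48 to −2.13
(autonomy and task variation carrying the large negative effects); the sex
coefficient is 0, because sex and gender are too collinear to identify
jointly — the sex–CES-D association then emerges through the sex–gender
correlation, as it plausibly does in reality.

Choices worth knowing about:

* one male working-hours category frequency is inconsistently printed in
  the published descriptives; the default (18.1%) is interpolated from the
  column sum and marked uncertain in the config documentation;
* a median split can only reproduce a below-50% "high" prevalence if the
  scores have probability mass *at* the median; low-group scores therefore
  concentrate at each condition's cut value with a small downward spread,
  and high-group scores sit strictly above — so the within-cohort median
  split recovers the generating indicator (exactly, with probability
  approaching 1 in n);
* partner prevalence (0.8) is not reported in the study descriptives and
  was set once to a realistic value for Dutch older workers;
* missing-at-random degradation is cellwise-Bernoulli with a logistic
  probability in sex and standardized age, intercept solved so the marginal
  rate matches the configured one (28% in the study-like setting);
* an optional gender × condition interaction coefficient exists solely so
  moderation tests can run against a known truth.

What the generator does **not** emulate: item-level CES-D and
working-condition questionnaires (only totals), multi-wave attrition,
survey weights, within-person longitudinal correlation, and any real-world
dependence between working conditions beyond that induced by the gender
group. Passing tests therefore demonstrate the *methods* are correct and
calibrated under the stated data-generating process, not that the
substantive findings generalize.

## Problem sizes used in the test suite

Simulation-based checks are sized to be decisive yet quick: tobit coverage
uses 500 replicates at n = 500; mediation null coverage 100 replicates at
n = 313 with 200 bootstrap resamples; ACME recovery and effect
decomposition n = 5,000; the MAR-plus-pooling calibration 20 replicates at
m = 10 imputations; closed-form convergence three cohorts of n = 50,000.

## Known limitations

Single-mediator models only (no joint multi-mediator decomposition, no
exposure–mediator interaction in the outcome model, no sensitivity analysis
for sequential ignorability); path-by-path estimation rather than a joint
SEM; percentile rather than BCa bootstrap; the gender index as a dichotomy
rather than a continuum. These mirror the scope of the analysis the package
operationalizes.
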