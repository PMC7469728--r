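---
title: "Methods of the cervical cancer risk meta-model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods of the cervical cancer risk meta-model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmeta)
```

## The problem

Case-control studies of cervical cancer risk factors in Chinese women report
odds ratios (ORs) for heterogeneous variable sets: different studies adjust
for different covariates, categorize continuous attributes into different
bins, and report variability in different forms (confidence intervals,
p-values, chi-square statistics, or nothing usable). A conventional
meta-analysis can pool ORs for *one* factor across studies, but cannot
synthesize evidence on *many* factors simultaneously into a risk prediction
for an individual woman. `ccmeta` implements a meta-model that does exactly
that: each study contributes a multiplicative risk equation calibrated
against the population incidence, and the per-study predictions for one
patient are pooled with a random-effects meta-analysis.

## Model

### Per-study risk equations

Let $R_0$ be the probability that a Chinese woman aged 18--85 has cervical
cancer at the time of assessment (default $R_0 = 0.000094$). Study $k$
reports odds ratios $OR_{jk}$ for the non-reference levels of the risk
factors it covers. Because those ORs are relative to the study's *reference
patient* (all factors at reference levels) while $R_0$ describes the
*average* woman, the study baseline divides $R_0$ by the relative risk of
the average woman versus the reference patient -- the product of the study's
ORs geometrically weighted by the population prevalence $p_l$ of each level:

$$R_{0k} = \frac{R_0}{\exp\left(\sum_{l} p_l \log OR_{lk}\right)}$$

The risk for patient $i$ multiplies back the ORs matching her own levels:

$$R_{ik} = R_{0k} \prod_{j} OR_{jk}.$$

Reference levels and "not applicable" entries (e.g. gestational factors of a
never-pregnant woman) contribute a multiplier of 1; factors the study does
not cover are skipped. This construction gives the calibration identity
$R_{0k} \cdot \exp(\sum_l p_l \log OR_{lk}) = R_0$, which holds to floating
precision for every study and is the package's first acceptance check.

### Standard-error imputation

Pooling needs a location $\mu_{jk}$ and standard error $\sigma_{jk}$ for
every log-OR. Estimates are assumed log-normal; exactly one imputation
method fires per estimate, by decreasing information content:

1. **Reported SE** -- used directly; for ratio-scale rows
   $\mu = \log OR - \sigma^2/2$ so the log-normal mean reproduces the
   reported OR.
2. **Regression coefficient** -- the OR point estimate is the unbiased
   log-normal mean $\exp(\mu + \sigma^2/2)$.
3. **95% CI** -- inverted from the bound parameterization
   $\exp(\mu + \sigma^2/2 \mp 1.96\sigma)$, giving
   $\sigma = (\log hi - \log lo)/(2 \cdot 1.96)$; the inversion is exact and
   round-trips to $10^{-10}$.
4. **p-value** -- the Altman--Bland approximation
   $z = -0.862 + \sqrt{0.743 - 2.404 \ln p}$, then $\sigma = |\mu/z|$, with
   the natural logarithm throughout. We verified numerically that $z$ tracks
   the exact normal quantile within 0.02 for $p \in [10^{-3}, 0.5]$ and
   degrades slowly below that (error $\approx 0.03$ at $p = 10^{-4}$), so
   the accuracy property is asserted on $[10^{-3}, 0.5]$.
5. **Chi-square + totals** -- the 2x2 contingency table is reconstructed
   from (case total, control total, reported ratio, $\chi^2$), and
   $\sigma^2 = 1/a + 1/b + 1/c + 1/d$ (Woolf).

### The contingency system and its two roots

The reconstruction solves the four equations $a + c = N_1$, $b + d = N_0$,
$\frac{a/(a+b)}{c/(c+d)} = \mathrm{ratio}$, and the Pearson $\chi^2$
identity. Cells are allowed to be fractional: summary statistics rounded for
publication generally admit no integer solution, so the solver targets
relative residuals below $10^{-8}$ instead. The ratio constraint ties $b$ to
$a$ in closed form, leaving a bracketed one-dimensional root search. Two
facts matter:

* The ratio equation uses the *cell-proportion* (risk-ratio) form even
  though the reported value is an odds ratio -- the source material conflates
  the two, and under the rare-disease reading they are close.
* The $\chi^2$ level set along the ratio-constrained curve generically
  crosses **twice**, and both crossings have their odds ratio on the same
  side of 1, so the system is not identifiable from the four summary
  statistics alone. The solver returns the root whose implied odds ratio is
  closest (log scale) to the supplied ratio -- the table with the smallest
  internal OR/RR discrepancy -- and handles the tangency case where the two
  roots coincide at the curve's maximum. Tests therefore assert that the
  returned table satisfies all four equations, not that it reproduces the
  exact cells of any particular generating table.

### Monte Carlo within-study uncertainty

The SE of a patient's log study-risk, $\sigma_{ik}$, is estimated by
simulation (default 10,000 replications): each log-OR is drawn
$N(\mu_{jk}, \sigma_{jk})$ and each *non-reference* prevalence estimate is
drawn from a Beta distribution with mean $p$ and SD $= \mathrm{CV} \cdot p$
(method-of-moments shapes, default CV 0.1). Three implementation choices:

* Only non-reference prevalences are sampled -- they are the quantities the
  sources actually report -- and the reference level holds the simplex
  remainder. (Sampling the reference complements directly would make the
  Beta parameterization infeasible already at CV 0.2 for common reference
  prevalences like 0.976 non-smokers.) In the rare replicate where a
  factor's non-reference draws sum to $\ge 1$ they are rescaled to preserve
  the simplex.
* Prevalence draws use inverse-CDF sampling from common uniforms, so
  configurations differing only in the CV share draws and their comparison
  is paired (common random numbers).
* Each (patient, study) simulation runs on an RNG substream derived
  deterministically from (seed, study id) and restores the caller's RNG
  state. Removing a study therefore never shifts another study's draws,
  which is what lets the leave-one-out analysis isolate removal effects from
  Monte Carlo noise.

The point estimate is plug-in (reported/imputed ORs, mean prevalences); the
simulation feeds only $\sigma_{ik}$. A CV that violates
$\mathrm{SD}^2 < p(1-p)$ raises an error advising a smaller CV.

### Random-effects pooling

Per-study log-risks are pooled with inverse-variance random effects. The
between-study variance $\tau^2$ uses the DerSimonian--Laird moment estimator
(the standard contemporaneous choice; REML is available via
`model_config(re_method = "reml")`). The pooled CI is the Wald interval on
the log scale, exponentiated; a single study passes through unchanged with
$\tau^2 = 0$ flagged. $R_0$ is held fixed in the simulation -- it is quoted
as a constant, and no variability for it is reported.

One consequence of the DL estimator worth stating plainly: when the moment
estimate of $\tau^2$ is positive, additional within-study variance (e.g.
from a larger prevalence CV) is largely *reallocated out of* $\hat\tau^2$
rather than added to the total -- with equal within-study variances the
pooled CI width is exactly invariant. The mean CI width therefore responds
monotonically but only weakly to the prevalence CV, and the sign of the
response depends on the heterogeneity regime: it is positive where
$\hat\tau^2$ sits at its zero floor and can be slightly negative where
heterogeneity dominates, as it does under the default synthetic conditions
(structural heterogeneity is large because studies covering HPV and studies
not covering it predict very different risks for an HPV-positive woman).
The sensitivity scan asserts the monotone response without fixing its sign.

## Sensitivity analysis

`leave_one_out()` removes one factor (from every study) or one study at a
time and reports, against the base case, **accuracy** (mean absolute
deviation of the predicted risk over profiles; a normalized variant divides
by the base-case risk) and **precision** (mean change in the relative CI
width $(hi - lo)/\mathrm{point}$, signed so that positive means the interval
got *narrower* after removal, matching the published sign convention).
Removing a factor can push a study below the two-factor eligibility
threshold, in which case the whole study drops out and the result notes it.
`scan_config()` varies the prevalence CV and the replication count.

## Synthetic data

The generators stand in for the model's real inputs (published per-study
estimates and population prevalence searches, which live in supplementary
material that is not redistributable) at the same dimensionality: 11
studies, 17 risk factors, about 130--140 reported risk-factor levels, each
study covering a partially overlapping subset of at least two factors.
Defaults were chosen once, for realism, and are the package's study
conditions:

* True ORs range from protective screening effects (0.4--0.6) through
  moderate behavioral and gestational effects (1.2--2.5) to a dominant HPV
  infection OR of 15, so that HPV's outsized influence on accuracy and
  precision is a reproducible property, and with per-estimate SEs scaled by
  $1 + 0.35\,|\log OR|$ -- extreme ORs in case-control data come from sparse
  exposed cells, whose Woolf variance grows with the effect size.
* Between-study SD of log-ORs 0.15; per-study case totals 120--400 and
  control totals 200--800; reporting patterns full CI / p-only /
  chi-square-only / coefficient-only with probabilities 0.55 / 0.20 / 0.15 /
  0.10, so every imputation path is exercised. Censored values are
  constructed to be exactly invertible where the pattern allows it;
  associations too weak to yield a usable chi-square fall back to a CI.
* Profiles are drawn from the population prevalence simplex with high-level
  dependencies: sexual debut from a truncated normal (mean 18.5, SD 2.2),
  first pregnancy rejected below debut + 9 months, first delivery 9 months
  after the pregnancy, 17.14% never pregnant (gestational factors "not
  applicable"), IUD duration only for IUD users, a lognormal cigarette index
  for the 2.4% of women who smoke. Continuous attributes are generated and
  then discretized into one shared canonical bin layout; the prevalence
  table is computed in closed form (or by numerical integration for the
  convolved pregnancy ages) from the same generative distributions, so
  empirical level frequencies match it up to sampling error.

What the generator does **not** emulate: real studies' correlated level
definitions across factors, publication bias, covariate adjustment effects,
or per-study bin layouts (cross-study level harmonization is the table
author's responsibility, and per-study bins would make patient levels
unmappable by design). Passing tests on synthetic data therefore show the
machinery is correct under the stated generative assumptions, not that the
default numbers describe any real population.

## Problem sizes used in the tests

The test suite runs the full pipeline at reduced simulation sizes chosen for
statistical power rather than fidelity: parameter recovery uses 100 profiles
at 300 replications (the plug-in risk ordering does not depend on the
replication count), the leave-one-out mirror uses 25 profiles at 600
replications, and the CV scan uses 25 profiles at 4,000 replications, where
the paired common-random-number design makes the systematic width response
(about $10^{-3}$ per 0.1 CV) clearly resolvable. The analytic
single-factor Monte Carlo check runs at the default 10,000 replications.

## Known limitations

* Risk is a point-in-time probability; no age-specific incidence, time
  trend, or causal interpretation.
* The "unmapped level" error is deliberate: the engine refuses to guess
  which study-specific category a patient level falls into.
* Tier-4 prevalence averaging over other studies' control groups is
  unweighted; whether the original procedure weighted by sample size is not
  documented.
* Pooled-OR rankings are a reporting feature (expert selection, not the
  ranking, decides what enters the risk engine); the pooling scale for the
  ranking ("weighted average of the OR" taken literally on the OR scale) is
  switchable to log-scale pooling via `pool_or(scale = "log")` because the
  literal reading is ambiguous.
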