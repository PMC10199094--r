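---
title: "From longitudinal retinal thickness to a diagnostic test for cognitive impairment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From longitudinal retinal thickness to a diagnostic test for cognitive impairment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinocog)
```

## The problem

The retina is developmentally an extension of the central nervous system, and
several neurodegenerative conditions leave measurable traces in it before
they are clinically obvious. `retinocog` implements a complete analysis chain
that turns two longitudinal measurements in mice — recognition memory scored
by the novel object recognition test (NORT) and retinal layer thicknesses
measured by optical coherence tomography (OCT) — into a binary diagnostic
test for cognitive impairment (CI), together with the full statistical
evaluation of that test.

The cognitive score is the **discrimination index**

$$DI = \frac{t_{novel} - t_{familiar}}{t_{total}},$$

bounded in $[-1, 1]$, with higher values indicating better recognition
memory. The retinal measurements are the thicknesses (in image pixels) of
the inner nuclear layer (INL), the outer nuclear layer (ONL), a composite of
the nerve fibre, ganglion cell and inner plexiform layers (NFL-GCL-IPL,
reported as one number because OCT cannot separate them in mice), and the
total retina (TR).

## The rolling monthly-change transform

Baseline DI and baseline thickness vary a lot between animals, so the
analysis works on *within-animal rates of change*. For each subject and each
adjacent pair of scheduled visits (4 to 6 and 6 to 9 months by default),

$$\Delta x = \frac{x(t_2) - x(t_1)}{t_2 - t_1}$$

gives a change per month (DI/month for cognition, px/month for thickness).
Twelve mice with three visits yield 24 such interval records, which the
analysis treats as exchangeable observations. Non-adjacent visit pairs are
never differenced, and a subject missing the middle visit simply contributes
no interval (the telescoping identity
$\sum_k \Delta x_k (t_{k+1} - t_k) = x(T) - x(0)$ is property-tested).

Eyes are averaged before any of this: thickness is taken as the arithmetic
mean of the two eyes at each visit, justified by a paired left-right
difference check (`eye_difference_test()`) that is run and reported before
averaging. A visit with one measured eye uses that eye, with a warning.

## Choosing the biomarker layer

TR thickness is excluded as a predictor from the start: it is a compound of
the individual layers and is already predicted almost entirely by the
NFL-GCL-IPL composite, so using it alongside the layers only injects
collinearity. The remaining candidate layers enter a multiple linear
regression with the DI monthly change as response,

$$\Delta DI = \beta_0 + \beta_1\,\Delta NFL + \beta_2\,\Delta INL +
\beta_3\,\Delta ONL + \varepsilon,$$

reported with per-coefficient two-sided t-tests, variance inflation factors
$VIF_j = 1/(1-R^2_j)$ (with $R^2_j$ from regressing predictor $j$ on the
others), a per-predictor partial (Type III) F partition next to the omnibus
ANOVA, and the parameter correlation matrix from the coefficient
covariance. For OLS, the partial F of a single predictor is exactly the
square of its coefficient t-statistic, so the per-predictor ANOVA p-values
equal the coefficient p-values — the convention the reporting layout
assumes.

The pipeline then selects the layer with the smallest coefficient p-value
(warning if none clears `alpha`). This is an explicit operationalisation of
a judgement call — picking the layer "most sensitive to cognition" after
inspecting the coefficients — and it is configurable via
`predictor_layers`.

## Thresholds: the DSM-V rule and forward interpolation

The DSM-V defines mild neurocognitive disorder as a cognitive test score
one to two standard deviations below the population mean, and major NCD as
more than two below. With $k = 1$ (the default, capturing mild and major
disease together) the CI threshold is

$$\theta_{DI} = \mu - k\,\sigma$$

over the observed DI monthly changes ($\sigma$ with the $n-1$ denominator;
the convention is not stated in the reporting this mirrors, and the sample
version is standard for a normative criterion). The biomarker threshold is
obtained by *forward substitution* into the fitted layer-change-on-DI-change
line:

$$\theta_{INL} = \hat\beta_1\,\theta_{DI} + \hat\beta_0 .$$

Inverting an x-on-y calibration line would be the textbook alternative, but
forward substitution into the y-on-x line is the procedure this pipeline is
designed to reproduce; with the canonical values
($\mu = -0.0579$, $\sigma = 0.1643$, line $y = 3.046x - 0.5284$) it gives
$\theta_{DI} = -0.2222$ DI/month and $\theta_{INL} = -1.205$ px/month.

A record is labelled **CI** when its DI change falls strictly below
$\theta_{DI}$. The diagnostic test has *test-of-health* polarity: a record
tests **positive** (predicted healthy) when its INL change is at or above
$\theta_{INL}$. Records exactly at a threshold classify to the
healthy/positive side — the rules are stated in terms of "above" and
"below", and ties take the benign reading consistently.

## Evaluating the test

Condition-positive is *no CI*, so in the 2×2 table a true positive is a
healthy record that tests positive. `diagnostic_report()` computes:

* **Fisher's exact test**, two-sided, by explicit hypergeometric
  enumeration: all tables with the observed margins are enumerated and the
  p-value is the sum of point probabilities at most that of the observed
  table, with a $1 + 10^{-7}$ relative guard against floating-point ties.
  This is the "method of small p-values" used by mainstream statistical
  software, and the implementation is equivalence-tested against
  `stats::fisher.test` on every 2×2 table with total at most 30.
* sensitivity, specificity, PPV, NPV; the diagnostic odds ratio
  $(tp \cdot tn)/(fp \cdot fn)$ and positive likelihood ratio
  $sens/(1-spec)$, both reported as `Infinity` when the denominator
  vanishes (serialized as the string `"Infinity"`); the relative risk as
  the proportion of condition-positives among test-positives over that
  among test-negatives — the definition that reproduces 2.0000 for the
  reference table; and the CI prevalence.
* Youden's $J = sens + spec - 1$ and the number needed to diagnose
  $1/J$; the number needed to misdiagnose $total/(fp+fn)$; the predictive
  summary index $PSI = PPV + NPV - 1$ and its reciprocal (number needed to
  predict). $1/J$ and $1/PSI$ are flagged undefined when the test is no
  better than chance; $0/0$ anywhere is flagged undefined rather than
  infinite.

## Group comparisons and the normality battery

Wherever two groups are compared (thickness between positive- and
negative-DI visits, changes between CI and no-CI records), dispatch follows
a strict gate: the pooled group-centred residuals must pass **all four** of
Anderson-Darling, D'Agostino-Pearson omnibus, Shapiro-Wilk and
Lilliefors-corrected Kolmogorov-Smirnov at $\alpha = 0.05$ (no multiplicity
correction — each test holds a veto, deliberately conservative toward the
nonparametric branch), and the two groups must pass an F-test of equal
variances. Only then is a pooled-variance two-tailed t-test used; otherwise
a two-tailed Mann-Whitney U (exact for combined $n \le 20$ without ties,
normal approximation with continuity and tie correction above that — the
switch point is conventional). The D'Agostino-Pearson omnibus test is
implemented in-package (skewness via the Johnson SU approximation, kurtosis
via Anscombe-Glynn, $K^2$ against $\chi^2_2$, requiring $n \ge 8$) and is
verified against an independent reference implementation on frozen vectors.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design so every stage is testable
without animal data: `n_mice` animals at ages 4, 6 and 9 months. Per mouse
and interval a DI monthly change $g \sim N(\mu_g, \sigma_g)$ is drawn
(defaults $-0.0579$ and $0.1643$ per month); the INL monthly change is

$$\Delta INL = a\,g + b + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma_\varepsilon),$$

with $a = 3.046$, $b = -0.5284$ and
$\sigma_\varepsilon = a\,\sigma_g\sqrt{(1-r^2)/r^2}$ chosen so the
model-implied $r^2 = a^2\sigma_g^2/(a^2\sigma_g^2+\sigma_\varepsilon^2)$
(see `implied_r2()`) equals 0.297. The generative direction is cognition →
retina: the DI is read as a surrogate of central nervous system health that
drives layer thickness, which makes the layer-change-on-DI-change
regression the correctly specified model. Interval changes are i.i.d.
within a mouse — no autocorrelation structure is imposed, matching the
exchangeable treatment of the 24 interval records.

Numerical choices worth knowing:

* **DI bounding.** DI is bounded by definition, so trajectories are kept in
  $[-1, 1]$. When a drawn trajectory leaves the range, the baseline is
  translated minimally to fit (a mouse that declines a lot is taken to have
  started higher) so the drawn changes are preserved exactly; only
  trajectories whose own range exceeds the scale are clamped stepwise, each
  clamp is counted, and the generator warns when more than
  `clamp_warn_frac` (default 10%) of steps clamp. The INL change is always
  computed from the *realized* (post-clamp) DI change, so the emitted data
  follow the coupling model exactly and parameter recovery is unbiased.
* **Measurement layers.** Each visit is emitted as two eyes with
  independent $N(0, 0.75^2)$ px perturbations; baselines and drifts for the
  uncoupled NFL-GCL-IPL and ONL layers (70 px, $-0.2$ px/month; 60 px,
  $-0.1$ px/month, noise SD 0.3 px/month) are round numbers of the right
  order for mouse OCT in image pixels; TR is the sum of the three layers
  plus an 8 px margin for the layers not individually segmented. Because
  eye averaging halves but does not remove the measurement noise, the
  *observed* INL-change regression $r^2$ in generated cohorts sits slightly
  below the latent 0.297 (typically 0.24-0.27); the suite checks it within
  $0.297 \pm 0.08$. Slope recovery is unaffected: across 100 replicate
  cohorts of 200 mice the 95% CI of the fitted coupling slope covers 3.046
  at the nominal rate.
* **Exploration times.** $t_{total} \sim U(20, 60)$ s with an exploration
  fraction in $U(0.7, 1)$, and novel/familiar times are solved from the DI
  so the index is realized exactly.
* Everything is deterministic given `seed`, and the caller's RNG state is
  restored.

What the generator does *not* emulate: within-mouse correlation of changes
across intervals, floor effects in animals with advanced degeneration
(where decline stops being linear), comorbid retinal disease, and
between-eye asymmetries. Tests passing on generated cohorts therefore
validate the statistical machinery under the model's own assumptions, not
the biology.

## The deterministic reference cohort

`reference_cohort()` is a *constructed*, not sampled, 12-mouse cohort whose
pipeline output lands exactly on a known answer, used for end-to-end
verification:

```{r reference, eval = FALSE}
res <- run_pipeline(reference_cohort(), k = 1)
as.matrix(res$contingency)
#>          test
#> condition positive negative
#>     no_CI       18        3
#>     CI           0        3
round(res$report$metrics["fisher_p"], 4)
#> 0.0099
```

The construction: 24 DI monthly changes are laid out with exact sample mean
$-0.0579$ and SD $0.1643$ (three standard scores below $-1$, three in
$(-1, 0)$ destined for negative tests, eighteen spread above); INL changes
are $3.046x - 0.5284$ plus residuals made orthogonal to the regressor and
scaled so $r^2 = 0.2970$ exactly (which also pins the slope p-value at
0.0059); nuisance layer changes are orthogonalised against both, so the
multiple regression selects the INL with certainty; trajectories are
integrated from baselines centred so every DI stays inside the bounds; and
the two eyes differ by a fixed $\pm 0.5$ px offset with alternating sign,
so averaging recovers the designed values exactly and the eye-difference
check is exactly null. All points keep a safety margin of at least 0.019
DI/month and 0.22 px/month from the thresholds, so classification is immune
to floating-point noise.

## Problem sizes and runtime choices

The test suite verifies the Fisher implementation against
`stats::fisher.test` on all 46,375 tables with total $\le 30$, runs
parameter recovery on 100 replicate cohorts of 200 mice, and checks
moment convergence on a 2,000-mouse cohort; these sizes give stable
verdicts while keeping the default suite in the minutes range. The
acceptance script's stochastic check uses one 2,000-mouse cohort (4,000
interval records).

## Known limitations

* The pipeline evaluates the diagnostic test on the same records used to
  derive the thresholds; there is no held-out validation, mirroring the
  desk-scale design it reproduces. Treat the reported sensitivity and
  specificity as in-sample.
* Interval records from the same mouse are treated as independent.
* No confidence intervals are attached to the diagnostic metrics, and no
  ROC-based cutoff optimisation is offered — thresholds come from the DSM-V
  rule, by design.
* Thickness stays in image pixels throughout; no micrometre conversion is
  attempted because no scale factor is assumed.
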