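---
title: "Population benefit of biomarker-guided detection and prevention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population benefit of biomarker-guided detection and prevention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popbenefit)
library(tibble)
```

## The problem

Association strength does not translate into intervention value. A marker
with odds ratio 50 for a 1%-prevalence disease, carried by 1% of the
population, has only 27% sensitivity; a marker carried by half the
population can have 66% sensitivity yet barely better-than-chance
specificity. Whether acting on such a marker helps or harms a *population*
depends on the absolute numbers of true and false positives and on what
each costs. This package implements a family of indices that put those
quantities on one scale.

## Binary markers: the exactly solved 2×2 table

All binary-marker indices are functions of the joint population fractions
$(a, b, c, d)$ of marker status × disease status. Rather than requiring the
full table, the package reconstructs it from three commonly reported
summaries — odds ratio $OR$, marker prevalence $p$, disease prevalence $w$
— by solving

$$(1 - OR)\,a^2 + \bigl[1 - p - w + OR(p + w)\bigr]\,a - OR\,p\,w = 0$$

for the true-positive fraction $a$ (then $b = p - a$, $c = w - a$,
$d = 1 - p - w + a$). For $OR \ne 1$ the quadratic has exactly one root in
the feasible interval $[\max(0, p + w - 1), \min(p, w)]$, because the odds
ratio is strictly monotone in $a$ there. Numerically, both roots are
obtained cancellation-free (the larger-magnitude branch first, the second
by Vieta's product), so extreme odds ratios do not lose precision;
$OR = 1$ is treated as exact independence ($a = pw$) rather than as a
near-singular quadratic. Degenerate prevalences (0 or 1) are rejected with
a classed error, as are zero margins when metrics are requested.

From the table: sensitivity $a/(a+c)$, specificity $d/(b+d)$, overall risk
$r_1 = a + c$, risk in the marker-negative group $r_2 = c/(c+d)$, and
$\mathrm{PAR\%} = 100\,(r_1 - r_2)/r_1$. A note on naming: $r_1$ and $r_2$
are sometimes labelled "prevalence" and "false negative fraction"; the
formulas implemented are the ones above — $r_2$ is *not*
$1 - \text{sensitivity} = c/(a+c)$, and the documentation keeps the
formula-based reading. In the rare-disease limit $w \to 0$ the closed forms
$sens = pOR/(pOR + 1 - p)$, $spec = 1 - p$,
$\mathrm{PAR\%} = 100\,p(OR-1)/(p(OR-1)+1)$ are provided; tests confirm
they agree with the solved table at $w = 10^{-6}$ to $10^{-4}$.

## The ratio of population benefit

The RPB aggregates gains and losses over the whole population relative to
its total stake:

$$\mathrm{RPB}_{det} = \frac{a f_1 - b f_2}{a f_1 + b f_2 + c f_1 + d f_2},
\qquad
\mathrm{RPB}_{prev} = \frac{a \eta f_1 - (a + b)\,\delta}
{a f_1 + b f_2 + c f_1 + d f_2}.$$

Parameters, with units and defaults:

* **f₁** (> 0, default 1): life-value gained per early-detected case. The
  natural unit is "one life equivalent", so everything else is measured
  against it.
* **f₂** (≥ 0): life-value lost per false-positive intervention; for
  surgical interventions, 1 − the quality-of-life utility weight of the
  procedure. The reference settings are 0.03 (esophageal adenocarcinoma),
  0.06 (breast cancer), 0.15 (ovarian cancer). No default — it is the one
  parameter a user must own.
* **η** ([0, 1]): fraction of would-be cases averted among treated
  carriers.
* **δ** (≥ 0): adverse-effect loss per *treated* person, interpreted as an
  absolute loss in the same life-value unit as $f_1$ (the printed
  prevention numerator applies it to $a$ and $b$ alike, which forces this
  reading; the alternative — δ as a fraction of $f_1$ — is not consistent
  with the formula). δ and $f_2$ are treated as commensurable for the same
  reason.
* **h** (≥ 0): per-person cost coefficient charged to every marker-positive
  subject in the absolute-gain forms $(a f_1 - b f_2) - h(a+b)$ and
  $(a\eta f_1 - (a+b)\delta) - h(a+b)$.

The denominator equals $f_1 w + f_2 (1 - w)$ — it depends only on disease
prevalence and the weights, never on the marker — so the RPB is bounded by
$f_1 w / (f_1 w + f_2(1-w))$, attained exactly by the perfect marker. With
$\delta = 0$ the prevention RPB cannot be negative: a harmless intervention
can at worst achieve nothing. Restricting the accounting to the diseased
group collapses the prevention RPB to $sens \cdot (\eta f_1 - \delta)/f_1$;
the factor is read as dimensionless net efficacy, the only interpretation
under which "sensitivity times a factor" is well-formed.

Net benefit is computed alongside as $NB = a - w_{nb} b$ per unit
population. The false-positive cost weight $w_{nb}$ is a free parameter; it
defaults to $f_2/f_1$, which makes $NB \cdot f_1$ coincide with the RPB
numerator and reproduces the reference grids (which do not state the weight
they used — the choice is documented here rather than hidden). Confounder
adjustment for every index is by stratification: the adjusted value is
$\sum_i p_i x_i$ with $p_i$ the proportion of cases in stratum $i$, with
weights validated to sum to 1 within $10^{-9}$.

## Continuous markers: the calibrated binormal model

A continuous marker is modelled by equal-variance Gaussians for the
diseased and non-diseased groups. Equal-variance normals imply a linear
logit, $\Pr(D = 1 \mid X = x) = \alpha + \beta x$ with
$\beta = (\mu_D - \mu_{\bar D})/\sigma^2$, so calibrating to a per-unit
odds ratio means

$$\mu_D = \mu_{\bar D} + \sigma^2 \ln OR.$$

This is the unique equal-variance-normal model consistent with that logit
statement; it reproduces the reference continuous grid's balanced
sensitivities (0.54 at OR 1.5 up to 0.84 at OR 50) and is validated in the
golden tests. Defaults $\mu_{\bar D} = 0$, $\sigma = 0.5$ match the
reference figures. Positive calls are made *above* the threshold
($P(X_D > c)$), and exact normal quantiles are used throughout — never
rounded critical values like 1.645.

Threshold policies: fixed sensitivity ($c = \mu_D - \sigma\Phi^{-1}(l)$),
fixed specificity ($c = \mu_{\bar D} + \sigma\Phi^{-1}(l)$), balanced
(sensitivity = specificity; the mean midpoint under equal variances), and
explicit. For non-Gaussian density pairs the same policies are solved by
monotone root finding (`uniroot` to $10^{-12}$ on the bracketing support).

All integral quantities have two routes: Gaussian closed forms (tail areas
via `pnorm`) and adaptive quadrature (`stats::integrate`, absolute and
relative tolerance $10^{-10}$, Gaussian support truncated at
$\mu \pm 10\sigma$ — a truncation error below $10^{-23}$, far under the
integration tolerance). Tests require the two routes to agree within
$10^{-8}$, and marker-dependent profiles $\eta(x)$, $\delta(x)$ are
additionally checked against Monte Carlo integration at three standard
errors. Dichotomising the marker at any threshold and pushing the induced
fractions $(w\,sens,\ (1-w)(1-spec),\ w(1-sens),\ (1-w)spec)$ through the
binary formulas reproduces the continuous closed forms to $10^{-12}$ —
the two halves of the package are one model.

$\eta(x)$ and $\delta(x)$ are evaluated pointwise with no smoothness
assumptions; profiles that depend on the densities themselves can simply
close over them.

## The cohort simulator

`simulate_binary_cohort()` draws subjects from the four-cell multinomial
over $(a, b, c, d)$ — not from conditional Bernoullis — so the empirical
odds ratio is unbiased for the generating one by construction.
`simulate_continuous_cohort()` draws Bernoulli($w$) disease labels and
class-conditional Gaussian marker values. Both are deterministic under a
seed, and cohorts round-trip through tab-delimited text with a JSON
parameter sidecar.

What the simulator emulates: sampling variability of a perfectly specified
generating model. What it does not: measurement error, covariate-dependent
confounding, missingness, model misspecification (non-Gaussian marker
shapes, unequal variances), or temporal structure. Passing recovery tests
therefore shows the estimators are *consistent plug-ins* for the analytic
indices, not that the indices are robust to real-data pathologies.
Recovery is tested on 20 scenarios spanning OR 1.5–50, marker prevalence
5–30% and disease prevalence 1–3% at $n = 10^5$ subjects per cohort, with
assertions at three standard errors (multinomial/delta-method SEs, fixed
seeds); the full test suite runs in well under a minute.

## Reproduction of the reference grids

The 30-row binary grid reproduces at printed precision in every cell but
one: PAR% at (OR 20, prevalence 70%) computes to 92.9251 and is printed
92.92 — truncated, not rounded — so the golden tolerance for that column is
0.0055 instead of 0.005.

The 18-row continuous grid is noisier at its source. The fixed-specificity
and balanced blocks reproduce closely (sensitivity/specificity within
0.0075, RPB within 0.003, PAR% within 0.3 points), and all independently
verified anchor cells (sensitivity 0.62 and RPB 0.119/NB 0.005 at fixed
specificity, OR 50; sensitivity 0.84 and breast-cancer RPB −0.020 at
balanced, OR 50; the 3%-prevalence RPB 0.176) match at printed precision.
The fixed-sensitivity block, however, is internally inconsistent as
printed: back-solving specificity from its own printed PAR% (at
sensitivity 0.95, $w = 0.01$) yields values that disagree with its printed
specificity column by more than the exact model does, and the exact model
falls between the two printed columns. No single consistent model can
reproduce both columns, so that block is compared at the measured noise
scale (specificity within 0.022, RPB within 0.016, PAR% within 0.9
points). The implementation stays exact; the tolerance describes the
source, not the code.

## Degenerate inputs and numerical tie-breaks

* Prevalences must lie strictly in (0, 1); rates like η in [0, 1]; all
  violations raise classed conditions (`popbenefit_invalid_input`,
  `popbenefit_degenerate`, `popbenefit_invalid_strata`,
  `popbenefit_integration_failure`, `popbenefit_solver_failure`).
* A threshold below the entire support (no marker-negative subjects) makes
  $q_{ue}$ undefined and errors rather than returning 0/0.
* If floating-point jitter ever places both quadratic roots inside the
  feasible interval (possible only at degenerate boundaries), the root
  whose implied table best reproduces the odds ratio is chosen.
* Rendered tables format with `sprintf("%.3f")`, which keeps signed zero
  (`-0.000` for a small negative value), matching the reference tables'
  display convention; unrendered tibbles always carry full precision.

## Limitations

* Point estimates only: no confidence intervals for OR, PAR% or RPB.
* Confounder adjustment is limited to stratified case-weighted averages —
  no Mantel–Haenszel or model-based adjustment.
* The continuous model is equal-variance binormal (or a user-supplied
  density pair); no unequal-variance parametric ROC, no density estimation
  from data.
* Net benefit is evaluated at a single cost weight, not as a full decision
  curve over threshold probabilities.
* $f_1$, $f_2$ are user inputs; estimating utility weights is out of scope.
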